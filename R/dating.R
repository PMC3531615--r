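# Substitution-rate calibration and divergence-time estimators.
#
# Three routes to a dated split:
#   D_A   = 2 mu T     (net nucleotide differences, mtDNA, years)
#   (dmu)^2 = 2 beta G (mean-size distance, microsatellites, generations)
#   D_SW  inverted numerically through its coalescent expectation
# All rates are per year (mu, sequences) or per locus per generation
# (beta, microsatellites); generation time converts generations to years.

#' Named microsatellite mutation-rate catalogue
#'
#' Literature point estimates commonly used for dating with microsatellite
#' distances: two human rates (fast 2.05e-3, slow 5.6e-4) and an average
#' mammalian rate (2.05e-4), all per locus per generation.
#'
#' @return named numeric vector.
#' @export
rate_catalogue <- function() {
  c(human_fast = 2.05e-3, human_slow = 5.6e-4, mammal_avg = 2.05e-4)
}

#' Calibrate a substitution rate from an outgroup split
#'
#' `mu = d_net / (2 T)` from the net between-species distance and the
#' fossil-calibrated split time. The rate CI combines the distance spread
#' (`d +/- 2 SD`) with the calibration CI extremes: lower rate from the
#' smallest distance over the oldest split, upper from the largest
#' distance over the youngest split.
#'
#' @param d_net net between-species distance (substitutions/site).
#' @param d_sd its standard deviation (0 for a point estimate).
#' @param T_split calibration split time in years.
#' @param T_ci length-2 vector `c(low, high)` in years, or NULL.
#' @param d_floor floor applied to `d_net - 2 d_sd` when it is
#'   non-positive (reported via a warning).
#' @return An object of class `calibration_result`: `mu`, `mu_ci`,
#'   `inputs`.
#' @export
calibrate_rate <- function(d_net, d_sd = 0, T_split, T_ci = NULL,
                           d_floor = 1e-6) {
  if (d_net <= 0 || T_split <= 0) stop("d_net and T_split must be > 0")
  if (is.null(T_ci)) T_ci <- c(T_split, T_split)
  if (T_ci[1] > T_split || T_ci[2] < T_split)
    stop("T_ci must bracket T_split")
  mu <- d_net / (2 * T_split)
  d_lo <- d_net - 2 * d_sd
  if (d_lo <= 0) {
    warning("d_net - 2 SD <= 0; clamping lower distance bound to ",
            d_floor)
    d_lo <- d_floor
  }
  d_hi <- d_net + 2 * d_sd
  mu_ci <- c(low = d_lo / (2 * T_ci[2]), high = d_hi / (2 * T_ci[1]))
  structure(list(mu = mu, mu_ci = mu_ci,
                 inputs = list(d_net = d_net, d_sd = d_sd,
                               T_split = T_split, T_ci = T_ci)),
            class = "calibration_result")
}

#' A degenerate calibration from a known substitution rate
#'
#' Wraps an externally known rate (e.g. the true rate of a simulation) as
#' a `calibration_result` with a point CI, for use with [time_from_da()].
#'
#' @param mu substitutions per site per year.
#' @return A `calibration_result`.
#' @export
known_rate_calibration <- function(mu) {
  if (mu <= 0) stop("mu must be > 0")
  structure(list(mu = mu, mu_ci = c(low = mu, high = mu),
                 inputs = list(d_net = NA, d_sd = NA, T_split = NA,
                               T_ci = c(NA, NA))),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Substitution rate:", format(x$mu, digits = 3),
      "subs/site/year\n  95% CI:", format(x$mu_ci[1], digits = 3), "-",
      format(x$mu_ci[2], digits = 3), "\n")
  invisible(x)
}

new_estimate <- function(method, T_years, ci = NULL, rate_used, gen_time = NA,
                         distance_value, extras = list()) {
  structure(list(method = method, T_years = T_years, ci = ci,
                 rate_used = rate_used, gen_time = gen_time,
                 distance_value = distance_value, extras = extras),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(x$method, "divergence estimate:", format_years(x$T_years), "years")
  if (!is.null(x$ci))
    cat("  (CI", format_years(x$ci[1]), "-", format_years(x$ci[2]), ")")
  cat("\n")
  invisible(x)
}

#' Divergence time from the net number of nucleotide differences
#'
#' `T = (D_A / L) / (2 mu)`. A negative `D_A` (possible for unstructured
#' data) is clamped to zero with a warning. The CI inverts the rate CI
#' (high rate gives the low time bound).
#'
#' @param D_A net nucleotide differences (count units).
#' @param L alignment length in sites.
#' @param cal a [calibrate_rate()] result.
#' @return A `divergence_estimate`.
#' @export
time_from_da <- function(D_A, L, cal) {
  if (D_A < 0) {
    warning("negative D_A clamped to 0 (no resolvable structure)")
    D_A <- 0
  }
  da_site <- D_A / L
  T_years <- da_site / (2 * cal$mu)
  ci <- c(low = da_site / (2 * cal$mu_ci[["high"]]),
          high = da_site / (2 * cal$mu_ci[["low"]]))
  new_estimate("DA", T_years, ci, rate_used = cal$mu,
               distance_value = D_A, extras = list(L = L))
}

#' Divergence time from (delta-mu)^2
#'
#' `G = dmu2 / (2 beta)` generations; `T = G * gen_time` years.
#'
#' @param dmu2 the (delta-mu)^2 distance (squared repeat units).
#' @param beta microsatellite mutation rate per locus per generation
#'   (a number or a name from [rate_catalogue()]).
#' @param gen_time generation time in years (default 6).
#' @return A `divergence_estimate`.
#' @export
time_from_dmu2 <- function(dmu2, beta, gen_time = 6) {
  beta <- resolve_rate(beta)
  if (dmu2 < 0) stop("dmu2 must be >= 0")
  G <- dmu2 / (2 * beta)
  new_estimate("DMU2", G * gen_time, NULL, rate_used = beta,
               gen_time = gen_time, distance_value = dmu2,
               extras = list(generations = G))
}

#' Effective population size from expected heterozygosity under the SMM
#'
#' Inverts the stepwise-mutation equilibrium
#' `He = 1 - 1 / sqrt(1 + 8 N_e beta)`:
#' `N_e = ((1 - He)^-2 - 1) / (8 beta)`.
#'
#' @param He expected heterozygosity in `[0, 1)`.
#' @param beta mutation rate per locus per generation.
#' @return `N_e` (diploid individuals).
#' @export
ne_from_he <- function(He, beta) {
  beta <- resolve_rate(beta)
  if (He < 0 || He >= 1) stop("He must be in [0, 1)")
  ((1 - He)^-2 - 1) / (8 * beta)
}

#' Forward D_SW expectation under drift and stepwise mutation
#'
#' `f(tau) = sqrt(2/pi) * [ sqrt(2 beta tau + 4 beta N_e)
#'           - 4 beta N_e / sqrt(8 beta N_e + 1) ]` by default; with
#' `literal_sqrt_first_term_only = TRUE` the `sqrt(2/pi)` factor is
#' applied to the first term only.
#'
#' @param tau time in generations.
#' @param beta mutation rate per locus per generation.
#' @param Ne effective population size.
#' @param literal_sqrt_first_term_only parenthesization switch (see
#'   Details in the methods vignette).
#' @return expected D_SW.
#' @export
dsw_expectation <- function(tau, beta, Ne,
                            literal_sqrt_first_term_only = FALSE) {
  drift <- 4 * beta * Ne / sqrt(8 * beta * Ne + 1)
  if (literal_sqrt_first_term_only)
    sqrt(2 / pi) * sqrt(2 * beta * tau + 4 * beta * Ne) - drift
  else
    sqrt(2 / pi) * (sqrt(2 * beta * tau + 4 * beta * Ne) - drift)
}

#' Divergence time from the stepwise-weighted distance D_SW
#'
#' Numerically inverts [dsw_expectation()] for `tau >= 0` by bisection
#' (bracket doubled until the expectation exceeds the observed distance,
#' up to tau = 1e9 generations). `N_e` is obtained from the mean of the
#' two populations' expected heterozygosities via [ne_from_he()]. When
#' the observed `D_SW` is at or below the tau = 0 expectation the time is
#' clamped to zero.
#'
#' @param dsw_value observed D_SW (repeat units).
#' @param He_X,He_Y expected heterozygosities of the two populations.
#' @param beta mutation rate per locus per generation.
#' @param gen_time generation time in years.
#' @param literal_sqrt_first_term_only see [dsw_expectation()].
#' @param tol relative bisection tolerance on tau.
#' @return A `divergence_estimate` with `N_e` and `tau` in `extras`.
#' @export
time_from_dsw <- function(dsw_value, He_X, He_Y, beta, gen_time = 6,
                          literal_sqrt_first_term_only = FALSE,
                          tol = 1e-8) {
  beta <- resolve_rate(beta)
  if (!is.finite(dsw_value)) stop("dsw must be finite")
  Ne <- ne_from_he(mean(c(He_X, He_Y)), beta)
  f <- function(tau) dsw_expectation(tau, beta, Ne,
                                     literal_sqrt_first_term_only)
  if (f(0) >= dsw_value) {
    tau <- 0
  } else {
    hi <- 1
    while (f(hi) < dsw_value) {
      hi <- hi * 2
      if (hi > 1e9) stop("D_SW inversion failed to bracket below tau = 1e9")
    }
    lo <- hi / 2
    if (hi == 1) lo <- 0
    while ((hi - lo) > tol * max(hi, 1)) {
      mid <- (lo + hi) / 2
      if (f(mid) < dsw_value) lo <- mid else hi <- mid
    }
    tau <- (lo + hi) / 2
  }
  new_estimate("DSW", tau * gen_time, NULL, rate_used = beta,
               gen_time = gen_time, distance_value = dsw_value,
               extras = list(Ne = Ne, tau = tau,
                             He_mean = mean(c(He_X, He_Y))))
}

resolve_rate <- function(beta) {
  if (is.character(beta)) {
    cat_ <- rate_catalogue()
    if (!beta %in% names(cat_))
      stop("unknown rate name '", beta, "'; use one of ",
           paste(names(cat_), collapse = ", "), " or a number")
    beta <- cat_[[beta]]
  }
  if (beta <= 0) stop("mutation rate must be > 0")
  unname(beta)
}

format_years <- function(x) {
  format(signif(x, 3), big.mark = " ", scientific = FALSE, trim = TRUE)
}

#' Tabulate divergence estimates
#'
#' Displayed years are rounded to 3 significant figures; full precision is
#' retained in the numeric columns.
#'
#' @param estimates list of `divergence_estimate` objects.
#' @return data.frame: `method`, `T_years` (full precision), `T_display`
#'   (3 significant figures), `ci_low`, `ci_high`, `rate_used`,
#'   `gen_time`, `distance_value`.
#' @export
report_estimates <- function(estimates) {
  if (length(estimates) == 0)
    return(data.frame(method = character(), T_years = numeric(),
                      T_display = numeric(), ci_low = numeric(),
                      ci_high = numeric(), rate_used = numeric(),
                      gen_time = numeric(), distance_value = numeric()))
  do.call(rbind, lapply(estimates, function(e)
    data.frame(method = e$method, T_years = e$T_years,
               T_display = signif(e$T_years, 3),
               ci_low = if (is.null(e$ci)) NA_real_ else unname(e$ci[1]),
               ci_high = if (is.null(e$ci)) NA_real_ else unname(e$ci[2]),
               rate_used = e$rate_used, gen_time = e$gen_time,
               distance_value = e$distance_value)))
}
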