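# Two-population split coalescent simulator with an optional outgroup
# lineage. Emits a sequence alignment (single non-recombining haploid
# locus, emulating mtDNA), a diploid microsatellite genotype table and a
# population map, together with the ground truth, so every pipeline stage
# can be validated without external data.
#
# Time runs backwards in generations. Demes X and Y coalesce internally
# until the split tau_gens ago, then merge into an ancestral deme. mtDNA
# is simulated with effective gene-copy number N/4 relative to the
# diploid size N (haploid, maternally inherited); autosomal
# microsatellites use 2N copies. No migration.

#' Simulation configuration
#'
#' Defaults emulate the central study scenario of the worked examples: two
#' populations of diploid effective size 5000 split 7000 generations ago
#' (42 000 years at 6 years/generation), sampled 11 + 29 individuals, a
#' 915-site mitochondrial fragment evolving at 5.76e-8 substitutions per
#' site per year with gamma rate heterogeneity (shape 0.118), an outgroup
#' lineage at 4.92 Ma, and 18 microsatellite loci mutating at 2.05e-4 per
#' generation under the SMM.
#'
#' @param n_X,n_Y sampled individuals per population (`n_Y = 0` gives a
#'   single-population simulation).
#' @param N_X,N_Y,N_anc diploid effective sizes.
#' @param tau_gens split time in generations (0 = panmixia).
#' @param outgroup_split_years outgroup divergence in years, or NULL for
#'   no outgroup.
#' @param seq list: `L`, `mu_site` (per site per year), `kappa` (ts/tv),
#'   `gamma_alpha` (NULL for equal site rates), `base_freqs` (ACGT).
#' @param msat list: `n_loci`, `beta` (per locus per generation), `model`
#'   ("SMM"/"TPM"), `p_ss`, `var_multi`, `root_size` (repeats).
#' @param gen_time years per generation.
#' @param mt_ne_factor mtDNA gene-copy number as a fraction of the diploid
#'   size N (default 0.25).
#' @param crash_X,crash_Y optional `list(time_gens, factor)`: the deme's
#'   size is `N / factor` more recently than `time_gens` ago (a recent
#'   `factor`-fold crash), `N` before.
#' @param seed RNG seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_X = 11, n_Y = 29, N_X = 5000, N_Y = 5000,
                       N_anc = 5000, tau_gens = 7000,
                       outgroup_split_years = 4.92e6,
                       seq = list(), msat = list(), gen_time = 6,
                       mt_ne_factor = 0.25, crash_X = NULL,
                       crash_Y = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  seq_def <- list(L = 915L, mu_site = 5.76e-8, kappa = 10,
                  gamma_alpha = 0.118,
                  base_freqs = c(A = 0.32, C = 0.27, G = 0.13, T = 0.28))
  msat_def <- list(n_loci = 18L, beta = 2.05e-4, model = "SMM",
                   p_ss = 0.95, var_multi = 12, root_size = 20L)
  seq <- utils::modifyList(seq_def, seq)
  msat <- utils::modifyList(msat_def, msat)
  if (n_X < 1 || n_Y < 0) stop("need n_X >= 1, n_Y >= 0")
  if (any(c(N_X, N_Y, N_anc) <= 0) || tau_gens < 0 || gen_time <= 0)
    stop("sizes, times and generation time must be positive")
  if (abs(sum(seq$base_freqs) - 1) > 1e-8)
    stop("base_freqs must sum to 1")
  structure(list(n_X = n_X, n_Y = n_Y, N_X = N_X, N_Y = N_Y,
                 N_anc = N_anc, tau_gens = tau_gens,
                 outgroup_split_years = outgroup_split_years,
                 seq = seq, msat = msat, gen_time = gen_time,
                 mt_ne_factor = mt_ne_factor, crash_X = crash_X,
                 crash_Y = crash_Y, seed = seed),
            class = "sim_config")
}

# piecewise-constant gene-copy number of a deme at backward time t
deme_size_at <- function(t, M, crash) {
  if (!is.null(crash) && t < crash$time_gens) M / crash$factor else M
}

# Structured coalescent for demes X/Y merging into anc at tau_gens.
# M_* are gene-copy numbers (pairwise coalescence rate 1/M per
# generation). Returns parent/time arrays; tips are 1..(k_x + k_y).
sim_split_tree <- function(k_x, k_y, M_x, M_y, M_anc, tau_gens,
                           crash_x = NULL, crash_y = NULL) {
  n <- k_x + k_y
  if (n < 2) stop("need at least 2 lineages")
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes); time <- numeric(n_nodes)
  active <- seq_len(n)
  deme <- c(rep("X", k_x), rep("Y", k_y))
  if (tau_gens == 0) deme[] <- "anc"
  nxt <- n + 1L
  t <- 0
  bounds <- as.numeric(sort(unique(c(
    if (!is.null(crash_x)) crash_x$time_gens,
    if (!is.null(crash_y)) crash_y$time_gens,
    if (tau_gens > 0) tau_gens))))
  bounds <- bounds[bounds > 0]
  repeat {
    if (length(active) == 1L) break
    sizes <- c(X = deme_size_at(t, M_x, crash_x),
               Y = deme_size_at(t, M_y, crash_y), anc = M_anc)
    k_d <- table(factor(deme, c("X", "Y", "anc")))
    rates <- as.numeric(k_d) * (as.numeric(k_d) - 1) / 2 / sizes
    tot <- sum(rates)
    later <- bounds[bounds > t]
    nb <- if (length(later) > 0) later[1] else Inf
    dt <- if (tot > 0) stats::rexp(1, tot) else Inf
    if (is.finite(nb) && t + dt >= nb) {
      t <- nb
      if (tau_gens > 0 && nb == tau_gens) deme[] <- "anc"
      next
    }
    if (!is.finite(dt)) stop("coalescent stalled (no rate, no boundary)")
    t <- t + dt
    d <- sample(c("X", "Y", "anc"), 1, prob = rates / tot)
    idx <- which(deme == d)
    pick <- sample(idx, 2)
    parent[active[pick]] <- nxt
    time[nxt] <- t
    active[pick[1]] <- nxt
    deme[pick[1]] <- d
    active <- active[-pick[2]]
    deme <- deme[-pick[2]]
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time, n_tips = n)
}

# attach an outgroup tip splitting at outgroup_gens; the outgroup tip
# becomes node n_tips_new = old n_nodes + 1 ... simpler: re-index with the
# outgroup as an extra tip id n+1 is impossible after the fact, so the
# caller passes include_outgroup to get tip ids 1..n for the ingroup and
# the returned `outgroup_tip` id.
attach_outgroup <- function(tree, outgroup_gens) {
  root <- length(tree$parent)
  if (tree$time[root] >= outgroup_gens)
    stop("outgroup split (", outgroup_gens, " gens) is younger than the ",
         "ingroup MRCA (", round(tree$time[root]), " gens)")
  og_tip <- root + 1L
  new_root <- root + 2L
  parent <- c(tree$parent, 0L, 0L)
  time <- c(tree$time, 0, outgroup_gens)
  parent[root] <- new_root
  parent[og_tip] <- new_root
  time[og_tip] <- 0
  list(parent = parent, time = time, n_tips = tree$n_tips,
       outgroup_tip = og_tip)
}

# Evolve sequences down a tree. Mutation events occur at rate
# mu_year * gen_time * r_s per site per generation (site factors r_s
# gamma-distributed with mean 1 when gamma_alpha is set); each event
# replaces the base by a different one with HKY-proportional jump
# probabilities (kappa-weighted transitions), so the realized per-site
# substitution rate is exactly mu_year regardless of base composition.
tip_sequences <- function(tree, L, mu_year, gen_time, kappa, gamma_alpha,
                          base_freqs) {
  bases <- c("A", "C", "G", "T")
  pf <- base_freqs / sum(base_freqs)
  ts_partner <- c(3L, 4L, 1L, 2L)
  jump <- matrix(0, 4, 4)
  for (i in 1:4) {
    w <- pf; w[i] <- 0
    w[ts_partner[i]] <- w[ts_partner[i]] * kappa
    jump[i, ] <- w / sum(w)
  }
  r <- if (is.null(gamma_alpha)) rep(1, L) else
    stats::rgamma(L, shape = gamma_alpha, rate = gamma_alpha)
  pr <- r / sum(r)
  n_nodes <- length(tree$parent)
  root <- n_nodes
  seqs <- matrix(0L, n_nodes, L)
  seqs[root, ] <- sample.int(4L, L, replace = TRUE, prob = pf)
  rate_total <- mu_year * gen_time * sum(r)
  for (v in seq(n_nodes - 1L, 1L)) {
    s <- seqs[tree$parent[v], ]
    branch <- tree$time[tree$parent[v]] - tree$time[v]
    nmut <- stats::rpois(1, rate_total * branch)
    if (nmut > 0) {
      sites <- sample.int(L, nmut, replace = TRUE, prob = pr)
      for (m in seq_len(nmut)) {
        cur <- s[sites[m]]
        s[sites[m]] <- sample.int(4L, 1L, prob = jump[cur, ])
      }
    }
    seqs[v, ] <- s
  }
  tips <- c(seq_len(tree$n_tips),
            if (!is.null(tree$outgroup_tip)) tree$outgroup_tip)
  matrix(bases[seqs[tips, , drop = FALSE]], nrow = length(tips))
}

# allele sizes (repeat units) for the tips of a tree under SMM/TPM with a
# reflecting floor at size 1
mutate_msat <- function(tree, beta, model, p_ss, var_multi, root_size) {
  q_geom <- tpm_q_geom(var_multi)
  n_nodes <- length(tree$parent)
  root <- n_nodes
  value <- integer(n_nodes)
  value[root] <- root_size
  for (v in seq(n_nodes - 1L, 1L)) {
    branch <- tree$time[tree$parent[v]] - tree$time[v]
    x <- value[tree$parent[v]]
    nmut <- stats::rpois(1, beta * branch)
    if (nmut > 0) {
      for (m in seq_len(nmut)) {
        s <- if (model == "TPM" && stats::runif(1) > p_ss)
          1L + stats::rgeom(1, q_geom) else 1L
        x <- x + if (stats::runif(1) < 0.5) s else -s
        if (x < 1L) x <- 2L - x  # reflect at the one-repeat floor
      }
    }
    value[v] <- x
  }
  value[seq_len(tree$n_tips)]
}

#' Simulate a two-population dataset with known truth
#'
#' Runs the split coalescent under a [sim_config()]: one non-recombining
#' sequence locus per individual (mtDNA analogue, gene-copy number
#' `mt_ne_factor * N`), diploid microsatellite genotypes (2N copies,
#' independent trees per locus), and an optional outgroup sequence.
#' Bit-reproducible from `(config, seed)`.
#'
#' @param cfg a [sim_config()].
#' @return list: `aln` ([SequenceAlignment], outgroup id `"OUT"` last when
#'   present), `gm` ([new_genotypes()]), `popmap`, `truth` (list with the
#'   config echo, tau_years, expected D_A `2 mu tau_years L`, expected He
#'   `1 - 1/sqrt(1 + 8 N beta)`, realized tree heights).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  n_x <- cfg$n_X; n_y <- cfg$n_Y
  ids_x <- sprintf("X%02d", seq_len(n_x))
  ids_y <- if (n_y > 0) sprintf("Y%02d", seq_len(n_y)) else character(0)
  ids <- c(ids_x, ids_y)
  popmap <- stats::setNames(rep(c("X", "Y"), c(n_x, n_y)), ids)

  # mtDNA: one copy per individual
  mt <- sim_split_tree(n_x, n_y,
                       M_x = cfg$mt_ne_factor * cfg$N_X,
                       M_y = cfg$mt_ne_factor * cfg$N_Y,
                       M_anc = cfg$mt_ne_factor * cfg$N_anc,
                       tau_gens = cfg$tau_gens,
                       crash_x = cfg$crash_X, crash_y = cfg$crash_Y)
  og_gens <- if (is.null(cfg$outgroup_split_years)) NULL else
    cfg$outgroup_split_years / cfg$gen_time
  if (!is.null(og_gens)) mt <- attach_outgroup(mt, og_gens)
  seq_mat <- tip_sequences(mt, cfg$seq$L, cfg$seq$mu_site, cfg$gen_time,
                           cfg$seq$kappa, cfg$seq$gamma_alpha,
                           cfg$seq$base_freqs)
  aln_ids <- c(ids, if (!is.null(og_gens)) "OUT")
  aln <- new_alignment(aln_ids, seq_mat)
  if (!is.null(og_gens)) popmap <- c(popmap, OUT = "outgroup")

  # microsatellites: two copies per individual, independent trees
  n_ind <- n_x + n_y
  a1 <- a2 <- matrix(NA_integer_, n_ind, cfg$msat$n_loci)
  for (l in seq_len(cfg$msat$n_loci)) {
    tr <- sim_split_tree(2 * n_x, 2 * n_y,
                         M_x = 2 * cfg$N_X, M_y = 2 * cfg$N_Y,
                         M_anc = 2 * cfg$N_anc, tau_gens = cfg$tau_gens,
                         crash_x = cfg$crash_X, crash_y = cfg$crash_Y)
    sizes <- mutate_msat(tr, cfg$msat$beta, cfg$msat$model,
                         cfg$msat$p_ss, cfg$msat$var_multi,
                         cfg$msat$root_size)
    # copies 2i-1, 2i belong to individual i within each deme block
    cx <- sizes[seq_len(2 * n_x)]
    a1[seq_len(n_x), l] <- cx[c(TRUE, FALSE)]
    a2[seq_len(n_x), l] <- cx[c(FALSE, TRUE)]
    if (n_y > 0) {
      cy <- sizes[2 * n_x + seq_len(2 * n_y)]
      a1[n_x + seq_len(n_y), l] <- cy[c(TRUE, FALSE)]
      a2[n_x + seq_len(n_y), l] <- cy[c(FALSE, TRUE)]
    }
  }
  gm <- new_genotypes(ids, sprintf("L%02d", seq_len(cfg$msat$n_loci)),
                      a1, a2, units = "repeats")
  tau_years <- cfg$tau_gens * cfg$gen_time
  truth <- list(config = cfg, tau_years = tau_years,
                expected_DA = 2 * cfg$seq$mu_site * tau_years * cfg$seq$L,
                expected_He_X = 1 - 1 / sqrt(1 + 8 * cfg$N_X *
                                               cfg$msat$beta),
                expected_He_Y = 1 - 1 / sqrt(1 + 8 * cfg$N_Y *
                                               cfg$msat$beta),
                mt_root_gens = max(mt$time))
  list(aln = aln, gm = gm, popmap = popmap, truth = truth)
}

#' Estimator-recovery experiment
#'
#' Repeatedly simulates datasets under one configuration, runs the three
#' dating estimators with the true rates supplied, and reports per-
#' replicate estimates and relative errors against the true split time.
#'
#' @param cfg a [sim_config()] (its seed is ignored; per-replicate seeds
#'   derive from `seed`).
#' @param n_reps number of replicates (>= 10).
#' @param seed master seed.
#' @return data.frame with one row per replicate: `tau_years_true`,
#'   `D_A`, `T_da`, `dmu2`, `T_dmu2`, `dsw`, `T_dsw` and the
#'   corresponding relative errors.
#' @export
recovery_experiment <- function(cfg, n_reps = 50, seed) {
  if (n_reps < 10) stop("recovery_experiment needs n_reps >= 10")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  mu <- cfg$seq$mu_site; beta <- cfg$msat$beta
  tau_years <- cfg$tau_gens * cfg$gen_time
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- (seed + 7919 * r) %% .Machine$integer.max
    sim <- simulate_dataset(cfg_r)
    da <- net_divergence_counts(sim$aln, sim$popmap, c("X", "Y"))
    cal <- known_rate_calibration(mu)
    t_da <- time_from_da(max(da, 0), cfg$seq$L, cal)$T_years
    dm <- delta_mu_squared(sim$gm, sim$popmap, c("X", "Y"))$dmu2
    t_dm <- time_from_dmu2(dm, beta, cfg$gen_time)$T_years
    ds <- dsw(sim$gm, sim$popmap, c("X", "Y"))$dsw
    he <- expected_heterozygosity(sim$gm, sim$popmap, "X")$mean
    he_y <- expected_heterozygosity(sim$gm, sim$popmap, "Y")$mean
    t_ds <- time_from_dsw(ds, he, he_y, beta, cfg$gen_time)$T_years
    data.frame(tau_years_true = tau_years, D_A = da, T_da = t_da,
               dmu2 = dm, T_dmu2 = t_dm, dsw = ds, T_dsw = t_ds)
  })
  out <- do.call(rbind, rows)
  if (tau_years > 0) {
    out$rel_err_da <- (out$T_da - tau_years) / tau_years
    out$rel_err_dmu2 <- (out$T_dmu2 - tau_years) / tau_years
    out$rel_err_dsw <- (out$T_dsw - tau_years) / tau_years
  }
  out
}
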