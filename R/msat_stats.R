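# Microsatellite diversity, differentiation and genetic distances.
#
# All allele-size-based statistics ((delta-mu)^2, D_SW, R_ST) are computed
# in repeat units when the GenotypeMatrix declares bp units with per-locus
# motif lengths (sizes divided by motif length), otherwise in the units
# given; the unit is recorded in outputs because (delta-mu)^2 scales
# quadratically with it.

analysis_sizes <- function(gm) {
  a1 <- gm$a1 * 1.0; a2 <- gm$a2 * 1.0
  unit <- gm$units
  if (identical(gm$units, "bp") && !is.null(gm$motif_length)) {
    ml <- gm$motif_length[gm$loci]
    if (anyNA(ml)) stop("motif_length missing for locus: ",
                        paste(gm$loci[is.na(ml)], collapse = ", "))
    a1 <- sweep(a1, 2, ml, "/"); a2 <- sweep(a2, 2, ml, "/")
    unit <- "repeats"
  }
  list(a1 = a1, a2 = a2, unit = unit)
}

gm_subset <- function(gm, ids) {
  idx <- match(ids, gm$individuals)
  if (anyNA(idx)) stop("unknown individual(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  gm$individuals <- gm$individuals[idx]
  gm$a1 <- gm$a1[idx, , drop = FALSE]
  gm$a2 <- gm$a2[idx, , drop = FALSE]
  gm
}

pop_individuals <- function(gm, popmap, pop) {
  ids <- intersect(gm$individuals, names(popmap)[popmap == pop])
  if (length(ids) == 0) stop("no genotyped individuals in population '",
                             pop, "'")
  ids
}

locus_allele_counts <- function(a1, a2, j) {
  x <- c(a1[, j], a2[, j])
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NULL)
  table(x)
}

unbiased_he <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Per-locus summaries for one population
#'
#' @param gm a [new_genotypes()] object.
#' @param popmap named character vector; NULL to use all individuals.
#' @param pop population label (ignored when `popmap` is NULL).
#' @return data.frame: `locus`, `n_genes`, `k`, `He`, `mean_size`,
#'   `var_size` (sizes in analysis units; attribute `unit`).
#' @export
locus_stats <- function(gm, popmap = NULL, pop = NULL) {
  if (!is.null(popmap)) gm <- gm_subset(gm, pop_individuals(gm, popmap, pop))
  sz <- analysis_sizes(gm)
  out <- lapply(seq_along(gm$loci), function(j) {
    x <- c(sz$a1[, j], sz$a2[, j]); x <- x[!is.na(x)]
    if (length(x) == 0)
      return(data.frame(locus = gm$loci[j], n_genes = 0L, k = 0L,
                        He = NA_real_, mean_size = NA_real_,
                        var_size = NA_real_))
    cnt <- table(x)
    data.frame(locus = gm$loci[j], n_genes = length(x),
               k = length(cnt), He = unbiased_he(cnt),
               mean_size = mean(x),
               var_size = if (length(x) > 1) stats::var(x) else 0)
  })
  out <- do.call(rbind, out)
  attr(out, "unit") <- sz$unit
  out
}

#' Unbiased expected heterozygosity per locus and its mean
#'
#' `He = n (1 - sum p_i^2) / (n - 1)` with `n` the observed allele copies.
#' Loci with fewer than two observed copies are skipped with a warning.
#'
#' @inheritParams locus_stats
#' @return list: `per_locus` (named vector), `mean`.
#' @export
expected_heterozygosity <- function(gm, popmap = NULL, pop = NULL) {
  st <- locus_stats(gm, popmap, pop)
  bad <- st$n_genes < 2
  if (any(bad))
    warning("skipping locus/loci with < 2 observed allele copies: ",
            paste(st$locus[bad], collapse = ", "))
  he <- stats::setNames(st$He[!bad], st$locus[!bad])
  list(per_locus = he, mean = mean(he))
}

# Nested method-of-moments ANOVA of per-copy values: populations /
# individuals / gene copies (diploid; missing pairs dropped). Returns the
# three variance components. Feeding allele indicators recovers the
# Weir-Cockerham theta components; feeding allele sizes gives the R_ST
# decomposition, so the two estimators share one engine and agree exactly
# on a biallelic equal-step locus.
nested_components <- function(y1, y2, pop) {
  ok <- !is.na(y1) & !is.na(y2)
  y1 <- y1[ok]; y2 <- y2[ok]; pop <- pop[ok]
  r <- length(unique(pop))
  n_ind <- length(y1)
  if (n_ind < 2 || r < 2) return(c(a = NA, b = NA, w = NA))
  ng <- tapply(rep(1, n_ind), pop, sum)
  N2 <- 2 * n_ind
  ybar_ind <- (y1 + y2) / 2
  ybar_pop <- tapply(y1 + y2, pop, sum) / (2 * ng)
  ybar <- sum(y1 + y2) / N2
  ss_w <- sum((y1 - ybar_ind)^2 + (y2 - ybar_ind)^2)
  ss_b <- sum(2 * (ybar_ind - ybar_pop[pop])^2)
  ss_a <- sum(2 * ng * (ybar_pop - ybar)^2)
  ms_w <- ss_w / n_ind
  ms_b <- ss_b / (n_ind - r)
  ms_a <- ss_a / (r - 1)
  nc <- (N2 - sum((2 * ng)^2) / N2) / (r - 1)
  sw <- ms_w
  sb <- (ms_b - ms_w) / 2
  sa <- (ms_a - ms_b) / nc
  c(a = sa, b = sb, w = sw)
}

shared_polymorphic_loci <- function(gm, popmap, pair) {
  idx <- gm$individuals %in% c(pop_individuals(gm, popmap, pair[1]),
                               pop_individuals(gm, popmap, pair[2]))
  keep <- logical(length(gm$loci))
  for (j in seq_along(gm$loci)) {
    for (p in pair) {
      ids <- pop_individuals(gm, popmap, p)
      sub <- match(ids, gm$individuals)
      if (sum(!is.na(gm$a1[sub, j])) == 0) {
        keep[j] <- NA
        break
      }
    }
    if (is.na(keep[j])) { keep[j] <- FALSE; next }
    cnt <- locus_allele_counts(gm$a1[idx, , drop = FALSE],
                               gm$a2[idx, , drop = FALSE], j)
    keep[j] <- !is.null(cnt) && length(cnt) > 1
  }
  keep
}

#' Weir-Cockerham multilocus theta (F_ST) for a pair of populations
#'
#' Theta estimated as the ratio of summed among-population variance
#' components to summed total components over loci and alleles, from a
#' nested populations/individuals/copies analysis of allele indicator
#' variables.
#'
#' @param gm a [new_genotypes()] object.
#' @param popmap named character vector (individual -> population).
#' @param pair length-2 character vector of population labels.
#' @return list: `theta`, `per_locus` (named vector), `loci_used`.
#' @export
wc_fst <- function(gm, popmap, pair) {
  ids <- c(pop_individuals(gm, popmap, pair[1]),
           pop_individuals(gm, popmap, pair[2]))
  if (length(pop_individuals(gm, popmap, pair[1])) < 2 ||
      length(pop_individuals(gm, popmap, pair[2])) < 2)
    stop("wc_fst needs >= 2 individuals per population")
  sub <- gm_subset(gm, ids)
  pop <- popmap[ids]
  keep <- shared_polymorphic_loci(gm, popmap, pair)
  if (!any(keep)) stop("no shared polymorphic loci between ",
                       pair[1], " and ", pair[2])
  num <- den <- 0
  per_locus <- stats::setNames(rep(NA_real_, sum(keep)), gm$loci[keep])
  for (j in which(keep)) {
    alleles <- names(locus_allele_counts(sub$a1, sub$a2, j))
    la <- lb <- lw <- 0
    for (al in alleles) {
      comp <- nested_components(as.numeric(sub$a1[, j] == as.numeric(al)),
                                as.numeric(sub$a2[, j] == as.numeric(al)),
                                pop)
      la <- la + comp["a"]; lb <- lb + comp["b"]; lw <- lw + comp["w"]
    }
    per_locus[gm$loci[j]] <- la / (la + lb + lw)
    num <- num + la; den <- den + la + lb + lw
  }
  list(theta = unname(num / den), per_locus = per_locus,
       loci_used = gm$loci[keep])
}

#' Allele-size-based R_ST for a pair of populations
#'
#' Same nested variance decomposition as [wc_fst()] applied to allele
#' sizes: the among-population component over the total size variance.
#'
#' @inheritParams wc_fst
#' @return list: `rst`, `per_locus`, `loci_used`, `unit`.
#' @export
rst <- function(gm, popmap, pair) {
  ids <- c(pop_individuals(gm, popmap, pair[1]),
           pop_individuals(gm, popmap, pair[2]))
  if (length(pop_individuals(gm, popmap, pair[1])) < 2 ||
      length(pop_individuals(gm, popmap, pair[2])) < 2)
    stop("rst needs >= 2 individuals per population")
  sub <- gm_subset(gm, ids)
  sz <- analysis_sizes(sub)
  pop <- popmap[ids]
  keep <- shared_polymorphic_loci(gm, popmap, pair)
  if (!any(keep)) stop("no shared polymorphic loci between ",
                       pair[1], " and ", pair[2])
  num <- den <- 0
  per_locus <- stats::setNames(rep(NA_real_, sum(keep)), gm$loci[keep])
  for (j in which(keep)) {
    comp <- nested_components(sz$a1[, j], sz$a2[, j], pop)
    per_locus[gm$loci[j]] <- comp["a"] / sum(comp)
    num <- num + comp["a"]; den <- den + sum(comp)
  }
  list(rst = unname(num / den), per_locus = per_locus,
       loci_used = gm$loci[keep], unit = sz$unit)
}

pop_locus_freqs <- function(gm, popmap, pop) {
  sub <- gm_subset(gm, pop_individuals(gm, popmap, pop))
  sz <- analysis_sizes(sub)
  lapply(seq_along(gm$loci), function(j) {
    x <- c(sz$a1[, j], sz$a2[, j]); x <- x[!is.na(x)]
    if (length(x) == 0) return(NULL)
    tab <- table(x)
    list(sizes = as.numeric(names(tab)), freq = as.numeric(tab) / sum(tab),
         mean = mean(x))
  })
}

#' Goldstein's (delta-mu)^2 distance between two populations
#'
#' Mean over shared loci of the squared difference in mean allele size.
#' Always non-negative; scales quadratically with the size unit, so the
#' unit is reported.
#'
#' @inheritParams wc_fst
#' @return list: `dmu2`, `per_locus`, `n_loci`, `unit`.
#' @export
delta_mu_squared <- function(gm, popmap, pair) {
  fx <- pop_locus_freqs(gm, popmap, pair[1])
  fy <- pop_locus_freqs(gm, popmap, pair[2])
  shared <- which(!vapply(fx, is.null, TRUE) & !vapply(fy, is.null, TRUE))
  if (length(shared) == 0) stop("no locus observed in both populations")
  per <- vapply(shared, function(j) (fx[[j]]$mean - fy[[j]]$mean)^2, 0)
  names(per) <- gm$loci[shared]
  list(dmu2 = mean(per), per_locus = per, n_loci = length(shared),
       unit = analysis_sizes(gm)$unit)
}

w_cross <- function(f1, f2) {
  # sum_i sum_j x_i y_j |s_i - s_j|
  as.numeric(f1$freq %*% abs(outer(f1$sizes, f2$sizes, "-")) %*% f2$freq)
}

#' Shriver's stepwise-weighted distance D_SW between two populations
#'
#' Per locus, the mean absolute allele-size difference between populations
#' minus the average of the within-population means; averaged over shared
#' loci. May be negative for very similar populations.
#'
#' @inheritParams wc_fst
#' @return list: `dsw`, `per_locus`, `n_loci`, `unit`.
#' @export
dsw <- function(gm, popmap, pair) {
  fx <- pop_locus_freqs(gm, popmap, pair[1])
  fy <- pop_locus_freqs(gm, popmap, pair[2])
  shared <- which(!vapply(fx, is.null, TRUE) & !vapply(fy, is.null, TRUE))
  if (length(shared) == 0) stop("no locus observed in both populations")
  per <- vapply(shared, function(j) {
    w_cross(fx[[j]], fy[[j]]) -
      (w_cross(fx[[j]], fx[[j]]) + w_cross(fy[[j]], fy[[j]])) / 2
  }, 0)
  names(per) <- gm$loci[shared]
  list(dsw = mean(per), per_locus = per, n_loci = length(shared),
       unit = analysis_sizes(gm)$unit)
}

#' Proportion-of-shared-alleles distance between two individuals
#'
#' Per co-typed locus the two genotypes share `min(count_a, count_b)`
#' copies of each allele (0, 1 or 2 in total); `D_PS` is one minus the
#' shared fraction over all co-typed loci. Individuals with no co-typed
#' locus get NA.
#'
#' @param gm a [new_genotypes()] object.
#' @param a,b individual ids.
#' @return `D_PS` in `[0, 1]`, or NA.
#' @export
shared_allele_distance <- function(gm, a, b) {
  ia <- match(a, gm$individuals); ib <- match(b, gm$individuals)
  if (is.na(ia) || is.na(ib)) stop("unknown individual id")
  dps_pair(gm$a1, gm$a2, ia, ib)
}

dps_pair <- function(a1, a2, ia, ib) {
  ok <- !is.na(a1[ia, ]) & !is.na(a1[ib, ])
  if (!any(ok)) return(NA_real_)
  shared <- 0
  for (j in which(ok)) {
    ga <- c(a1[ia, j], a2[ia, j]); gb <- c(a1[ib, j], a2[ib, j])
    for (al in unique(ga))
      shared <- shared + min(sum(ga == al), sum(gb == al))
  }
  1 - shared / (2 * sum(ok))
}

#' Full D_PS matrix across individuals
#'
#' Individuals missing more than half of the loci are excluded with a
#' warning. The matrix can be exported with [write_distance_matrix()] for
#' external neighbor-joining.
#'
#' @param gm a [new_genotypes()] object.
#' @param max_missing maximum tolerated fraction of missing loci.
#' @return symmetric numeric matrix.
#' @export
dps_matrix <- function(gm, max_missing = 0.5) {
  miss_frac <- rowMeans(is.na(gm$a1))
  drop <- miss_frac > max_missing
  if (any(drop)) {
    warning("excluding individual(s) missing > ", 100 * max_missing,
            "% of loci from D_PS matrix: ",
            paste(gm$individuals[drop], collapse = ", "))
    gm <- gm_subset(gm, gm$individuals[!drop])
  }
  n <- length(gm$individuals)
  D <- matrix(0, n, n, dimnames = list(gm$individuals, gm$individuals))
  if (n >= 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- dps_pair(gm$a1, gm$a2, i, j)
  D
}
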