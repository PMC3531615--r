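# Sequence-level diversity, distance and differentiation statistics.
#
# Difference counting policy: sites with N in either sequence are excluded
# pairwise; ordinary gap columns are excluded pairwise; a column produced by
# recode_indel() is an exception — there, gap vs base scores exactly one
# difference (one indel event).

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' Pairwise raw difference counts
#'
#' Counts nucleotide differences between every pair of sequences with
#' pairwise deletion of N/gap sites, scoring a recoded indel column as one
#' event (presence vs absence).
#'
#' @param aln a [SequenceAlignment].
#' @return n x n symmetric integer-valued matrix of difference counts.
#' @export
pairwise_diff_counts <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat)
  indel_cols <- aln$indel_events$col[!is.na(aln$indel_events$col)]
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    xi <- mat[i, ]
    for (j in (i + 1):n) {
      xj <- mat[j, ]
      usable <- xi != "N" & xj != "N"
      gap_either <- xi == "-" | xj == "-"
      ordinary <- usable & !gap_either
      d <- sum(xi[ordinary] != xj[ordinary])
      if (length(indel_cols) > 0) {
        ic <- indel_cols[usable[indel_cols]]
        d <- d + sum(xor(xi[ic] == "-", xj[ic] == "-"))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Collapse an alignment into haplotypes
#'
#' Identical sequences share a haplotype, numbered in first-occurrence
#' order (`H01`, `H02`, ...). N is never silently compatible with a base:
#' sequences containing N only merge when identical character-for-character,
#' and such haplotypes are flagged in the `has_N` column.
#'
#' @param aln a [SequenceAlignment].
#' @return data.frame with columns `haplotype`, `n`, `has_N` and a
#'   `members` list-column of sample ids; attribute `assignment` maps each
#'   sample to its haplotype.
#' @export
haplotype_collapse <- function(aln) {
  if (length(aln$ids) == 0) stop("empty alignment")
  key <- apply(aln$mat, 1, paste, collapse = "")
  first <- !duplicated(key)
  levs <- key[first]
  idx <- match(key, levs)
  hap_id <- sprintf("H%02d", seq_along(levs))
  out <- data.frame(haplotype = hap_id,
                    n = as.integer(tabulate(idx, length(levs))),
                    has_N = grepl("N", levs, fixed = TRUE))
  out$members <- split(aln$ids, factor(idx, levels = seq_along(levs)))
  attr(out, "assignment") <- stats::setNames(hap_id[idx], aln$ids)
  out
}

#' Haplotype diversity with its standard deviation
#'
#' `Hd = n (1 - sum p_i^2) / (n - 1)` over haplotype frequencies, with the
#' Nei (1987, eq. 8.12) sampling variance.
#'
#' @param aln a [SequenceAlignment] with at least two sequences.
#' @return list with `Hd` and `sd`.
#' @export
haplotype_diversity <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("haplotype diversity undefined for n < 2")
  haps <- haplotype_collapse(aln)
  p <- haps$n / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  Hd <- n * (1 - s2) / (n - 1)
  V <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = Hd, sd = sqrt(max(V, 0)))
}

#' Nucleotide diversity (per site) with its standard deviation
#'
#' Mean pairwise difference count (recoded indel = one event) divided by
#' the alignment length, with the Nei (1987, eq. 10.7) total variance
#' (sampling plus stochastic).
#'
#' @param aln a [SequenceAlignment] with at least two sequences.
#' @return list with `pi` and `sd`.
#' @export
nucleotide_diversity <- function(aln) {
  n <- length(aln$ids)
  if (n < 2) stop("nucleotide diversity undefined for n < 2")
  L <- aln_length(aln)
  D <- pairwise_diff_counts(aln)
  k_bar <- mean(D[upper.tri(D)])
  pi <- k_bar / L
  V <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, sd = sqrt(max(V, 0)))
}

#' Summary diversity statistics for one alignment
#'
#' @param aln a [SequenceAlignment].
#' @return list: `n`, `n_hap`, `n_seg` (polymorphic nucleotide sites,
#'   excluding recoded indel columns), `n_indel` (recoded indel events
#'   segregating), `Hd`, `Hd_sd`, `pi`, `pi_sd`.
#' @export
diversity_stats <- function(aln) {
  n <- length(aln$ids)
  haps <- haplotype_collapse(aln)
  seg <- function(col) {
    obs <- col[col != "N" & col != "-"]
    length(unique(obs)) > 1
  }
  is_indel_col <- seq_len(aln_length(aln)) %in% aln$indel_events$col
  nseg <- sum(vapply(which(!is_indel_col),
                     function(j) seg(aln$mat[, j]), TRUE))
  n_indel <- sum(vapply(which(is_indel_col), function(j) {
    col <- aln$mat[, j]
    any(col == "-") && any(col != "-" & col != "N")
  }, TRUE))
  # substitution polymorphism can co-occur with the indel at its retained
  # column; count it too
  nseg <- nseg + sum(vapply(which(is_indel_col),
                            function(j) seg(aln$mat[, j]), TRUE))
  hd <- if (n >= 2) haplotype_diversity(aln) else list(Hd = NA, sd = NA)
  pi <- if (n >= 2) nucleotide_diversity(aln) else list(pi = NA, sd = NA)
  list(n = n, n_hap = nrow(haps), n_seg = nseg, n_indel = n_indel,
       Hd = hd$Hd, Hd_sd = hd$sd, pi = pi$pi, pi_sd = pi$sd)
}

#' Distance model parameters
#'
#' @param model `"TN93"` or `"p"` (proportion of differing sites).
#' @param gamma_alpha gamma shape for among-site rate variation, or NULL
#'   for no rate heterogeneity. The mitochondrial analyses in the worked
#'   examples use 0.118.
#' @param count_indel_events should recoded indel columns contribute one
#'   difference to count-based statistics?
#' @export
distance_params <- function(model = "TN93", gamma_alpha = NULL,
                            count_indel_events = TRUE) {
  model <- match.arg(model, c("TN93", "p"))
  if (!is.null(gamma_alpha) && gamma_alpha <= 0)
    stop("gamma_alpha must be > 0")
  list(model = model, gamma_alpha = gamma_alpha,
       count_indel_events = count_indel_events)
}

tn93_pair <- function(xi, xj, gamma_alpha = NULL) {
  use <- xi != "N" & xj != "N" & xi != "-" & xj != "-"
  xi <- xi[use]; xj <- xj[use]
  L <- length(xi)
  if (L == 0) stop("no comparable sites for pair")
  base <- c("A", "C", "G", "T")
  f <- (table(factor(xi, base)) + table(factor(xj, base))) / (2 * L)
  f <- as.numeric(f); names(f) <- base
  gR <- f["A"] + f["G"]; gY <- f["C"] + f["T"]
  diff <- xi != xj
  ts1 <- sum(diff & ((xi == "A" & xj == "G") | (xi == "G" & xj == "A"))) / L
  ts2 <- sum(diff & ((xi == "C" & xj == "T") | (xi == "T" & xj == "C"))) / L
  Q <- sum(diff) / L - ts1 - ts2
  if (gR <= 0 || gY <= 0) {
    # degenerate composition: fall back to counting; only sensible when
    # no changes of the absent class occurred
    if (sum(diff) == 0) return(0)
    stop("saturation error: degenerate base composition for pair")
  }
  k1 <- 2 * f["A"] * f["G"] / gR
  k2 <- 2 * f["T"] * f["C"] / gY
  k3 <- 2 * (gR * gY - f["A"] * f["G"] * gY / gR -
               f["T"] * f["C"] * gR / gY)
  w1 <- if (k1 > 0) 1 - ts1 / k1 - Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - ts2 / k2 - Q / (2 * gY) else 1
  w3 <- 1 - Q / (2 * gR * gY)
  if (k1 > 0 && w1 <= 0 || k2 > 0 && w2 <= 0 || w3 <= 0)
    stop("saturation error: TN93 logarithm argument <= 0 for pair")
  if (is.null(gamma_alpha)) {
    d <- -(if (k1 > 0) k1 * log(w1) else 0) -
      (if (k2 > 0) k2 * log(w2) else 0) - k3 * log(w3)
  } else {
    a <- gamma_alpha
    g <- function(w) a * (w^(-1 / a) - 1)
    d <- (if (k1 > 0) k1 * g(w1) else 0) +
      (if (k2 > 0) k2 * g(w2) else 0) + k3 * g(w3)
  }
  unname(d)
}

#' Tamura-Nei (TN93) distance between two sequences
#'
#' Substitutions per site under the TN93 model, optionally with
#' gamma-distributed among-site rate variation (each `-log(w)` term becomes
#' `alpha * (w^(-1/alpha) - 1)`). Base frequencies are estimated from the
#' two sequences being compared; sites with gap or N in either sequence
#' are excluded pairwise. A logarithm argument at or below zero raises a
#' saturation error naming the pair.
#'
#' @param s1,s2 character strings or character vectors of bases.
#' @param params a [distance_params()] list.
#' @return Distance in substitutions per site.
#' @export
tn93_distance <- function(s1, s2, params = distance_params()) {
  if (length(s1) == 1) s1 <- strsplit(toupper(s1), "")[[1]]
  if (length(s2) == 1) s2 <- strsplit(toupper(s2), "")[[1]]
  if (length(s1) != length(s2)) stop("sequences have unequal lengths")
  if (params$model == "p") {
    use <- s1 != "N" & s2 != "N" & s1 != "-" & s2 != "-"
    if (!any(use)) stop("no comparable sites for pair")
    return(sum(s1[use] != s2[use]) / sum(use))
  }
  tn93_pair(s1, s2, params$gamma_alpha)
}

#' Pairwise model-corrected distance matrix for an alignment
#'
#' @param aln a [SequenceAlignment].
#' @param params a [distance_params()] list.
#' @return Symmetric numeric matrix of distances.
#' @export
distance_matrix <- function(aln, params = distance_params()) {
  n <- length(aln$ids)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- tryCatch(tn93_distance(aln$mat[i, ], aln$mat[j, ], params),
                  error = function(e)
                    stop("distance failed for pair (", aln$ids[i], ", ",
                         aln$ids[j], "): ", conditionMessage(e)))
    D[i, j] <- D[j, i] <- d
  }
  D
}

subset_alignment <- function(aln, keep) {
  idx <- if (is.character(keep)) match(keep, aln$ids) else keep
  if (anyNA(idx)) stop("unknown sample id(s) in subset")
  aln$ids <- aln$ids[idx]
  aln$mat <- aln$mat[idx, , drop = FALSE]
  aln
}

group_ids <- function(popmap, group, ids) {
  out <- intersect(ids, names(popmap)[popmap == group])
  out
}

#' Raw, within-group and net between-group distances
#'
#' The net distance subtracts the mean within-group diversity from the raw
#' mean between-group distance, correcting for polymorphism already present
#' in the common ancestor. Both raw and net values are returned so either
#' reading of a "corrected" between-species distance is inspectable.
#'
#' @param aln a [SequenceAlignment].
#' @param popmap named character vector (sample -> population).
#' @param groups length-2 character vector of population labels.
#' @param params a [distance_params()] list.
#' @return list: `d_xy_raw`, `d_within_x`, `d_within_y`, `d_net`.
#' @export
between_group_distance <- function(aln, popmap, groups,
                                   params = distance_params()) {
  ix <- group_ids(popmap, groups[1], aln$ids)
  iy <- group_ids(popmap, groups[2], aln$ids)
  if (length(ix) == 0 || length(iy) == 0)
    stop("empty group in between_group_distance")
  D <- distance_matrix(subset_alignment(aln, c(ix, iy)), params)
  a <- seq_along(ix); b <- length(ix) + seq_along(iy)
  dxy <- mean(D[a, b, drop = FALSE])
  wx <- if (length(a) >= 2) mean(D[a, a][upper.tri(D[a, a])]) else 0
  wy <- if (length(b) >= 2) mean(D[b, b][upper.tri(D[b, b])]) else 0
  list(d_xy_raw = dxy, d_within_x = wx, d_within_y = wy,
       d_net = dxy - (wx + wy) / 2)
}

#' Net number of nucleotide differences between two populations
#'
#' `D_A = mean between-group difference count - mean within-group
#' difference count`, in raw count units (uncorrected; a recoded indel
#' contributes one event). May be negative for unstructured data.
#'
#' @inheritParams between_group_distance
#' @return `D_A` in difference-count units.
#' @export
net_divergence_counts <- function(aln, popmap, groups) {
  ix <- group_ids(popmap, groups[1], aln$ids)
  iy <- group_ids(popmap, groups[2], aln$ids)
  if (length(ix) < 2 || length(iy) < 2)
    stop("net_divergence_counts needs >= 2 sequences per group")
  D <- pairwise_diff_counts(subset_alignment(aln, c(ix, iy)))
  a <- seq_along(ix); b <- length(ix) + seq_along(iy)
  kxy <- mean(D[a, b, drop = FALSE])
  kx <- mean(D[a, a][upper.tri(D[a, a])])
  ky <- mean(D[b, b][upper.tri(D[b, b])])
  kxy - (kx + ky) / 2
}

phist_from_d2 <- function(d2, grp) {
  N <- nrow(d2)
  labs <- unique(grp)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  ng <- numeric(length(labs))
  for (k in seq_along(labs)) {
    idx <- which(grp == labs[k])
    ng[k] <- length(idx)
    if (length(idx) >= 2) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  G <- length(labs)
  ss_among <- ss_total - ss_within
  df_a <- G - 1; df_w <- N - G
  ms_a <- ss_among / df_a
  ms_w <- if (df_w > 0) ss_within / df_w else 0
  n_prime <- (N - sum(ng^2) / N) / (G - 1)
  sig_a <- (ms_a - ms_w) / n_prime
  tot <- sig_a + ms_w
  if (tot <= 0) 0 else sig_a / tot
}

#' AMOVA-based pairwise Phi-ST with a permutation test
#'
#' Partitions squared model-corrected distances among and within two
#' populations; significance by permuting population labels. With all
#' distances zero Phi-ST is defined as 0.
#'
#' @inheritParams between_group_distance
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list: `phist`, `p`, `n_perm`, `seed`.
#' @export
pairwise_phist <- function(aln, popmap, groups, params = distance_params(),
                           n_perm = 10000, seed = NULL) {
  ix <- group_ids(popmap, groups[1], aln$ids)
  iy <- group_ids(popmap, groups[2], aln$ids)
  if (length(ix) < 2 || length(iy) < 2)
    stop("pairwise_phist needs >= 2 sequences per group")
  sub <- subset_alignment(aln, c(ix, iy))
  grp <- rep(groups, c(length(ix), length(iy)))
  d2 <- distance_matrix(sub, params)^2
  obs <- phist_from_d2(d2, grp)
  p <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (phist_from_d2(d2, sample(grp)) >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  list(phist = obs, p = p, n_perm = n_perm, seed = seed)
}

log_table_prob <- function(tab) {
  # multivariate hypergeometric probability of a contingency table given
  # its margins
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte-Carlo exact test of population differentiation
#'
#' Conditional test on a haplotype-by-population count table: the statistic
#' is the multivariate hypergeometric probability of the table given its
#' margins; the p-value is the proportion of tables sampled under the null
#' (fixed margins) with probability no larger than observed, with a +1/+1
#' correction.
#'
#' @param tab matrix of counts, populations x haplotypes.
#' @param n_perm number of sampled null tables.
#' @param seed RNG seed.
#' @return list: `p`, `log_prob_obs`, `n_perm`, `seed`.
#' @export
differentiation_test <- function(tab, n_perm = 10000, seed = NULL) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2) stop("differentiation test needs >= 2 populations")
  if (ncol(tab) < 2 || sum(colSums(tab) > 0) < 2)
    return(list(p = 1, log_prob_obs = 0, n_perm = n_perm, seed = seed))
  obs <- log_table_prob(tab)
  p <- with_seed(seed, {
    sims <- stats::r2dtable(n_perm, rowSums(tab), colSums(tab))
    lp <- vapply(sims, log_table_prob, 0)
    (sum(lp <= obs + 1e-9) + 1) / (n_perm + 1)
  })
  list(p = p, log_prob_obs = obs, n_perm = n_perm, seed = seed)
}

#' Haplotype counts per population
#'
#' @inheritParams between_group_distance
#' @return matrix populations x haplotypes.
#' @export
haplotype_table <- function(aln, popmap) {
  assign <- attr(haplotype_collapse(aln), "assignment")
  pops <- popmap[aln$ids]
  if (anyNA(pops)) stop("sample(s) missing from population map: ",
                        paste(aln$ids[is.na(pops)], collapse = ", "))
  table(population = pops, haplotype = assign[aln$ids])
}
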