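# Independent oracles used here: naive double loops for difference counts
# and diversity, ape::dist.dna for TN93, hand-computed AMOVA components,
# and fisher.test for the 2x2 differentiation table.

naive_pi <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat); L <- ncol(mat)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2) / L
}

test_that("haplotype collapse groups identical sequences in input order", {
  aln <- make_aln(rep("ACGT", 4))
  h <- haplotype_collapse(aln)
  expect_equal(nrow(h), 1L)
  expect_equal(h$n, 4L)

  aln2 <- make_aln(c("AC", "AG", "AC"))
  h2 <- haplotype_collapse(aln2)
  expect_equal(h2$haplotype, c("H01", "H02"))
  expect_equal(h2$n, c(2L, 1L))
  expect_equal(attr(h2, "assignment")[["s03"]], "H01")

  # sequences containing N are flagged, never merged with a resolved base
  aln3 <- make_aln(c("ACGT", "ACGN"))
  h3 <- haplotype_collapse(aln3)
  expect_equal(nrow(h3), 2L)
  expect_equal(h3$has_N, c(FALSE, TRUE))
})

test_that("haplotype diversity follows the small-sample formula", {
  expect_equal(haplotype_diversity(make_aln(c("AAAA", "AAAA")))$Hd, 0)
  # n = 4 all distinct: Hd = (4/3)(1 - 4/16) = 1
  hd <- haplotype_diversity(make_aln(c("AA", "AC", "AG", "AT")))
  expect_equal(hd$Hd, 1)
  expect_equal(hd$sd, sqrt(2 / (4 * 3) *
                             (2 * 2 * (4 * (1/64) - (1/4)^2) +
                                1/4 - 1/16)))
  expect_error(haplotype_diversity(make_aln("ACGT")), "n < 2")
})

test_that("nucleotide diversity matches a naive pairwise-count oracle", {
  expect_equal(nucleotide_diversity(make_aln(rep("ACGTACGTAC", 3)))$pi, 0)
  aln <- make_aln(c("ACGTACGTAC", "ACGTACGTAT"))
  expect_equal(nucleotide_diversity(aln)$pi, 0.1)
  set.seed(21)
  seqs <- replicate(7, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                             collapse = ""))
  expect_equal(nucleotide_diversity(make_aln(seqs))$pi, naive_pi(seqs))
})

test_that("TN93 distances agree with ape and reduce to K80", {
  p <- distance_params("TN93")
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT", p), 0)

  set.seed(31)
  for (alpha in list(NULL, 0.118, 1)) {
    s1 <- sample(c("A", "C", "G", "T"), 500, TRUE, c(.3, .25, .15, .3))
    s2 <- s1
    idx <- sample(500, 45)
    s2[idx] <- sample(c("A", "C", "G", "T"), 45, TRUE)
    bin <- ape::as.DNAbin(matrix(tolower(rbind(s1, s2)), 2))
    ref <- if (is.null(alpha)) ape::dist.dna(bin, model = "TN93") else
      ape::dist.dna(bin, model = "TN93", gamma = alpha)
    got <- tn93_distance(s1, s2, distance_params("TN93",
                                                 gamma_alpha = alpha))
    expect_equal(got, as.numeric(ref), tolerance = 1e-10)
  }

  # equal base frequencies and balanced transition types: TN93 equals K80
  s1 <- strsplit("ACGTACGTACGTACGTACGTACGTACGTACGT", "")[[1]]
  s2 <- s1
  # swap pairs so pooled base frequencies stay exactly 1/4 each:
  # A<->G at sites 1/3 and C<->T at sites 2/4
  s2[1:4] <- c("G", "T", "A", "C")
  bin <- ape::as.DNAbin(matrix(tolower(rbind(s1, s2)), 2))
  expect_equal(tn93_distance(s1, s2, p),
               as.numeric(ape::dist.dna(bin, model = "K80")),
               tolerance = 1e-10)
})

test_that("TN93 excludes gap/N sites pairwise and flags saturation", {
  # the N/gap sites mask the only differences
  expect_equal(tn93_distance("ACGTACGT", "NCGTAC-T", distance_params()), 0)
  sat1 <- paste(rep(c("A", "C", "G", "T"), 10), collapse = "")
  sat2 <- paste(rep(c("C", "A", "T", "G"), 10), collapse = "")
  expect_error(tn93_distance(sat1, sat2, distance_params()), "saturation")
})

test_that("p-distance mode is monotone in added differing sites", {
  p <- distance_params("p")
  base <- rep("A", 20)
  last <- 0
  for (k in 1:6) {
    other <- base
    other[seq_len(k)] <- "C"
    d <- tn93_distance(paste(base, collapse = ""),
                       paste(other, collapse = ""), p)
    expect_gt(d, last)
    last <- d
  }
})

test_that("net between-group distances subtract within diversity", {
  aln <- make_aln(c("AAAA", "AAAA", "TTTT", "TTTT"))
  pm <- split_popmap(aln$ids, 2)
  bg <- between_group_distance(aln, pm, c("X", "Y"), distance_params("p"))
  expect_equal(bg$d_xy_raw, 1)
  expect_equal(bg$d_net, 1)
  expect_equal(bg$d_within_x, 0)

  # identical composition in the two groups: for this finite sample the
  # unbiased within-group mean (over distinct pairs) exceeds the raw
  # between mean, so d_net = 0.5 - 1 = -0.5 exactly; only the
  # expectation over random samples is zero (tested via D_A below)
  aln2 <- make_aln(c("AAAA", "TTTT", "AAAA", "TTTT"))
  bg2 <- between_group_distance(aln2, split_popmap(aln2$ids, 2),
                                c("X", "Y"), distance_params("p"))
  expect_equal(bg2$d_net, -0.5)
  expect_error(between_group_distance(aln, pm, c("X", "Z"),
                                      distance_params("p")), "empty")
})

test_that("D_A equals the fixed inter-haplotype difference count", {
  aln <- make_aln(c("AAAAAA", "AAAAAA", "AAATTT", "AAATTT"))
  pm <- split_popmap(aln$ids, 2)
  expect_equal(net_divergence_counts(aln, pm, c("X", "Y")), 3)
  expect_error(net_divergence_counts(aln, pm, c("X", "Z")), ">= 2")
})

test_that("D_A is centred on zero for arbitrary splits of one population", {
  das <- sapply(1:20, function(r) {
    cfg <- sim_config(n_X = 6, n_Y = 6, N_X = 2000, N_Y = 2000,
                      N_anc = 2000, tau_gens = 0,
                      outgroup_split_years = NULL,
                      seq = list(L = 400, mu_site = 1e-6,
                                 gamma_alpha = NULL),
                      msat = list(n_loci = 0), seed = 900 + r)
    sim <- simulate_dataset(cfg)
    net_divergence_counts(sim$aln, sim$popmap, c("X", "Y"))
  })
  # within-population diversity here is ~2 differences per pair
  expect_lt(abs(mean(das)), 0.25)
})

test_that("Phi-ST matches hand-computed AMOVA components on a 3+3 toy", {
  aln <- make_aln(c("AAAA", "AAAA", "AAAT", "TTTA", "TTTA", "TTTT"))
  pm <- split_popmap(aln$ids, 3)
  res <- pairwise_phist(aln, pm, c("X", "Y"), distance_params("p"),
                        n_perm = 200, seed = 5)
  # Hand derivation with squared p-distances (sites / 4):
  #   within-group d^2 sums: 2 x (0 + 1/16 + 1/16) ; between: 6.8125
  #   SS_total = 7.0625/6, SS_within = 2 x 0.125/3, n' = 3
  #   sigma_a = (1.09375 - 1/48)/3, Phi = 51.5/54.5
  expect_equal(res$phist, 51.5 / 54.5, tolerance = 1e-12)
  expect_lt(res$p, 0.2)
})

test_that("Phi-ST hits its boundary cases", {
  # identical haplotype composition: Phi ~ 0, p ~ 1
  aln <- make_aln(c("AAAA", "TTTT", "AAAA", "TTTT"))
  res <- pairwise_phist(aln, split_popmap(aln$ids, 2), c("X", "Y"),
                        distance_params("p"), n_perm = 99, seed = 2)
  expect_lt(res$phist, 1e-12)
  expect_gt(res$p, 0.5)

  # groups fixed for two different haplotypes: Phi = 1
  aln2 <- make_aln(c("AAAA", "AAAA", "TTTT", "TTTT"))
  res2 <- pairwise_phist(aln2, split_popmap(aln2$ids, 2), c("X", "Y"),
                         distance_params("p"), n_perm = 99, seed = 2)
  expect_equal(res2$phist, 1)

  # all-zero distances: Phi defined as 0
  aln3 <- make_aln(rep("AAAA", 4))
  res3 <- pairwise_phist(aln3, split_popmap(aln3$ids, 2), c("X", "Y"),
                         distance_params("p"), n_perm = 99, seed = 2)
  expect_equal(res3$phist, 0)
})

test_that("the exact differentiation test matches enumeration extremes", {
  # 10 vs 10 fixed for different haplotypes; Fisher's exact two-sided
  # probability-based p is 2/choose(20,10) ~ 1.1e-5
  tab <- rbind(c(10, 0), c(0, 10))
  res <- differentiation_test(tab, n_perm = 10000, seed = 7)
  expect_lte(res$p, 0.001)
  expect_lt(stats::fisher.test(tab)$p.value, 1e-4)

  # identical composition: p near 1
  tab2 <- rbind(c(20, 20), c(20, 20))
  expect_gt(differentiation_test(tab2, n_perm = 2000, seed = 7)$p, 0.5)

  # single haplotype: p = 1 by convention
  expect_equal(differentiation_test(cbind(c(5, 5)), n_perm = 100,
                                    seed = 1)$p, 1)
})

test_that("the differentiation test statistic is label-symmetric", {
  set.seed(12)
  tab <- matrix(rpois(8, 5) + 1, 2, 4)
  p1 <- differentiation_test(tab, n_perm = 3000, seed = 3)$p
  p2 <- differentiation_test(tab[2:1, ], n_perm = 3000, seed = 3)$p
  expect_equal(p1, p2)
})

test_that("diversity summaries count indel events separately", {
  rc <- 12660:12672
  aln <- make_aln(c("AAAAATTTAAAAA", "AAAAA---AAAAA", "AAAAATTTAAAAC"),
                  ref_coords = rc)
  aln <- recode_indel(aln, c(12665, 12667))
  st <- diversity_stats(aln)
  expect_equal(st$n, 3L)
  expect_equal(st$n_hap, 3L)
  expect_equal(st$n_indel, 1L)
  expect_equal(st$n_seg, 1L)  # the final-column substitution
})
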