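# Oracles here: direct allele-count loops for He, the published
# Weir-Cockerham per-allele a/b/c formulas coded independently, and
# explicit O(k^2) double loops for (delta-mu)^2 / D_SW / D_PS.

wc_theta_oracle <- function(counts1, counts2) {
  # counts*: list(per-individual genotype matrix rows) -> here we take
  # two matrices of allele pairs (n_i x 2) for one locus
  alleles <- sort(unique(c(counts1, counts2)))
  n1 <- nrow(counts1); n2 <- nrow(counts2)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p1 <- mean(counts1 == al); p2 <- mean(counts2 == al)
    h1 <- mean(xor(counts1[, 1] == al, counts1[, 2] == al))
    h2 <- mean(xor(counts2[, 1] == al, counts2[, 2] == al))
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

test_that("expected heterozygosity matches a direct-count oracle", {
  # monomorphic locus
  gm <- make_gm(list(list(c(10, 10)), list(c(10, 10))))
  expect_equal(unname(expected_heterozygosity(gm)$per_locus), 0)
  # two heterozygotes sharing no alleles: He = (4/3)(1 - 4/16) = 1
  gm2 <- make_gm(list(list(c(10, 12)), list(c(14, 16))))
  expect_equal(unname(expected_heterozygosity(gm2)$per_locus), 1)
  # random fixture vs brute force
  gm3 <- random_gm(30, 5, seed = 17)
  he <- expected_heterozygosity(gm3)$per_locus
  for (j in seq_len(5)) {
    x <- c(gm3$a1[, j], gm3$a2[, j])
    n <- length(x)
    brute <- n / (n - 1) * (1 - sum((table(x) / n)^2))
    expect_equal(unname(he[j]), brute, tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham theta matches the published component formulas", {
  set.seed(41)
  g1 <- matrix(sample(c(10L, 12L, 14L), 16, TRUE, c(.5, .3, .2)), 8, 2)
  g2 <- matrix(sample(c(10L, 12L, 14L), 12, TRUE, c(.2, .2, .6)), 6, 2)
  geno <- c(lapply(seq_len(8), function(i) list(g1[i, ])),
            lapply(seq_len(6), function(i) list(g2[i, ])))
  gm <- make_gm(geno)
  pm <- split_popmap(gm$individuals, 8)
  got <- wc_fst(gm, pm, c("X", "Y"))$theta
  expect_equal(got, wc_theta_oracle(g1, g2), tolerance = 1e-9)
})

test_that("F_ST and R_ST hit their boundary values", {
  fixed <- make_gm(c(lapply(1:5, function(i) list(c(10L, 10L))),
                     lapply(1:5, function(i) list(c(20L, 20L)))))
  pm <- split_popmap(fixed$individuals, 5)
  expect_equal(wc_fst(fixed, pm, c("X", "Y"))$theta, 1)
  expect_equal(rst(fixed, pm, c("X", "Y"))$rst, 1)

  # identical size distributions: both near zero (slightly negative is
  # expected from the method-of-moments components)
  same <- make_gm(rep(list(list(c(10L, 12L)), list(c(12L, 14L))), 10))
  pm2 <- split_popmap(same$individuals, 10)
  expect_lt(abs(wc_fst(same, pm2, c("X", "Y"))$theta), 0.1)
  expect_lt(abs(rst(same, pm2, c("X", "Y"))$rst), 0.1)

  mono <- make_gm(lapply(1:6, function(i) list(c(10L, 10L))))
  expect_error(wc_fst(mono, split_popmap(mono$individuals, 3),
                      c("X", "Y")), "polymorphic")
})

test_that("F_ST equals R_ST on a biallelic one-step locus", {
  set.seed(42)
  geno <- lapply(1:14, function(i)
    list(sample(c(10L, 11L), 2, TRUE, prob = if (i <= 7) c(.8, .2)
                else c(.3, .7))))
  gm <- make_gm(geno)
  pm <- split_popmap(gm$individuals, 7)
  expect_equal(wc_fst(gm, pm, c("X", "Y"))$theta,
               rst(gm, pm, c("X", "Y"))$rst, tolerance = 1e-9)
})

test_that("(delta-mu)^2 matches brute force and its trivial cases", {
  fixed <- make_gm(c(lapply(1:3, function(i) list(c(10L, 10L))),
                     lapply(1:3, function(i) list(c(13L, 13L)))))
  pm <- split_popmap(fixed$individuals, 3)
  expect_equal(delta_mu_squared(fixed, pm, c("X", "Y"))$dmu2, 9)

  same <- make_gm(rep(list(list(c(10L, 14L))), 6))
  expect_equal(delta_mu_squared(same, split_popmap(same$individuals, 3),
                                c("X", "Y"))$dmu2, 0)

  gm <- random_gm(12, 5, seed = 23)
  pm3 <- split_popmap(gm$individuals, 6)
  got <- delta_mu_squared(gm, pm3, c("X", "Y"))
  brute <- mean(sapply(1:5, function(j) {
    mx <- mean(c(gm$a1[1:6, j], gm$a2[1:6, j]))
    my <- mean(c(gm$a1[7:12, j], gm$a2[7:12, j]))
    (mx - my)^2
  }))
  expect_equal(got$dmu2, brute, tolerance = 1e-12)
  expect_gte(got$dmu2, 0)
})

test_that("D_SW matches an O(k^2) double-loop oracle", {
  fixed <- make_gm(c(lapply(1:3, function(i) list(c(10L, 10L))),
                     lapply(1:3, function(i) list(c(17L, 17L)))))
  pm <- split_popmap(fixed$individuals, 3)
  expect_equal(dsw(fixed, pm, c("X", "Y"))$dsw, 7)

  same <- make_gm(rep(list(list(c(10L, 14L))), 6))
  expect_equal(dsw(same, split_popmap(same$individuals, 3),
                   c("X", "Y"))$dsw, 0)

  gm <- random_gm(10, 4, seed = 29)
  pm3 <- split_popmap(gm$individuals, 5)
  got <- dsw(gm, pm3, c("X", "Y"))$dsw
  per <- sapply(1:4, function(j) {
    x <- c(gm$a1[1:5, j], gm$a2[1:5, j])
    y <- c(gm$a1[6:10, j], gm$a2[6:10, j])
    wxy <- wxx <- wyy <- 0
    for (a in x) for (b in y) wxy <- wxy + abs(a - b)
    for (a in x) for (b in x) wxx <- wxx + abs(a - b)
    for (a in y) for (b in y) wyy <- wyy + abs(a - b)
    wxy / (length(x) * length(y)) -
      (wxx / length(x)^2 + wyy / length(y)^2) / 2
  })
  expect_equal(got, mean(per), tolerance = 1e-12)
})

test_that("distances are symmetric in the population pair", {
  gm <- random_gm(12, 5, seed = 57)
  pm <- split_popmap(gm$individuals, 6)
  expect_equal(delta_mu_squared(gm, pm, c("X", "Y"))$dmu2,
               delta_mu_squared(gm, pm, c("Y", "X"))$dmu2)
  expect_equal(dsw(gm, pm, c("X", "Y"))$dsw,
               dsw(gm, pm, c("Y", "X"))$dsw)
  expect_equal(wc_fst(gm, pm, c("X", "Y"))$theta,
               wc_fst(gm, pm, c("Y", "X"))$theta)
  expect_equal(rst(gm, pm, c("X", "Y"))$rst,
               rst(gm, pm, c("Y", "X"))$rst)
})

test_that("D_PS counts shared allele copies per co-typed locus", {
  gm <- make_gm(list(list(c(146L, 150L), c(100L, 102L)),
                     list(c(146L, 150L), c(100L, 102L)),
                     list(c(160L, 162L), c(120L, 122L)),
                     list(c(146L, 146L), NA)))
  expect_equal(shared_allele_distance(gm, "i01", "i02"), 0)
  expect_equal(shared_allele_distance(gm, "i01", "i03"), 1)
  # heterozygote {146,150} vs homozygote {146,146}: one shared copy at the
  # single co-typed locus
  expect_equal(shared_allele_distance(gm, "i01", "i04"), 0.5)
})

test_that("the D_PS matrix drops mostly-missing individuals", {
  gm <- random_gm(6, 4, seed = 3)
  gm$a1[6, 1:3] <- gm$a2[6, 1:3] <- NA_integer_
  expect_warning(D <- dps_matrix(gm), "i06")
  expect_equal(dim(D), c(5L, 5L))
  expect_true(all(abs(D - t(D)) < 1e-12))
  expect_true(all(diag(D) == 0))
  tmp <- withr::local_tempfile()
  write_distance_matrix(D, tmp)
  expect_equal(read_distance_matrix(tmp), round(D, 6), tolerance = 1e-9)
})

test_that("size-based statistics convert bp to repeat units", {
  geno <- c(lapply(1:3, function(i) list(c(100L, 100L))),
            lapply(1:3, function(i) list(c(112L, 112L))))
  gm_bp <- make_gm(geno)
  gm_bp$units <- "bp"
  gm_bp$motif_length <- c(L01 = 4L)
  pm <- split_popmap(gm_bp$individuals, 3)
  # 12 bp apart = 3 repeats apart
  expect_equal(delta_mu_squared(gm_bp, pm, c("X", "Y"))$dmu2, 9)
  expect_equal(dsw(gm_bp, pm, c("X", "Y"))$dsw, 3)
  expect_equal(delta_mu_squared(gm_bp, pm, c("X", "Y"))$unit, "repeats")
})
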