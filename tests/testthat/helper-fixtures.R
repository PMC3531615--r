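# Small programmatic fixtures shared across test files.

make_aln <- function(seqs, ids = sprintf("s%02d", seq_along(seqs)),
                     ref_coords = NULL) {
  new_alignment(ids, seqs, ref_coords)
}

# diploid genotype fixture: `geno` is a list of individuals, each a list
# of length-2 allele vectors (or NA for a missing pair), one per locus
make_gm <- function(geno, loci = NULL, ids = NULL) {
  n <- length(geno)
  L <- length(geno[[1]])
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) for (j in seq_len(L)) {
    g <- geno[[i]][[j]]
    if (!anyNA(g)) { a1[i, j] <- g[1]; a2[i, j] <- g[2] }
  }
  new_genotypes(ids, loci, a1, a2)
}

random_gm <- function(n_ind, n_loci, pool = 8:20, seed = 1) {
  set.seed(seed)
  geno <- lapply(seq_len(n_ind), function(i)
    lapply(seq_len(n_loci), function(j) sample(pool, 2, replace = TRUE)))
  make_gm(geno)
}

even_popmap <- function(ids, labels = c("A", "B")) {
  setNames(rep(labels, length.out = length(ids))[order(seq_along(ids))],
           ids)
}

split_popmap <- function(ids, n_first, labels = c("X", "Y")) {
  setNames(rep(labels, c(n_first, length(ids) - n_first)), ids)
}
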