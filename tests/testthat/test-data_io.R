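test_that("the five-block concatenation schema covers 915 columns", {
  sch <- default_schema_915()
  expect_equal(attr(sch, "total"), 915L)
  expect_equal(sch$length, c(29L, 431L, 234L, 155L, 66L))
  rc <- schema_ref_coords(sch)
  expect_length(rc, 915L)
  # strictly increasing within each block
  for (i in seq_len(nrow(sch))) {
    blk <- rc[rc >= sch$start[i] & rc <= sch$end[i]]
    expect_true(all(diff(blk) == 1L))
  }
})

test_that("reference/column coordinate conversion is a two-way inverse", {
  rc <- schema_ref_coords(default_schema_915())
  set.seed(11)
  pos <- sample(rc, 50)
  cols <- ref_to_col(rc, pos)
  expect_equal(col_to_ref(rc, cols), pos)
  cols2 <- sample(seq_along(rc), 50)
  expect_equal(ref_to_col(rc, col_to_ref(rc, cols2)), cols2)
  expect_true(is.na(ref_to_col(rc, 1L)))  # outside any block
})

test_that("FASTA reading validates lengths, characters and schema", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGA"), tmp)
  aln <- read_alignment(tmp)
  expect_s3_class(aln, "SequenceAlignment")
  expect_equal(aln_length(aln), 4L)
  expect_equal(aln$ids, c("a", "b"))

  writeLines(c(">a", "ACGT", ">b", "ACGTA"), tmp)
  expect_error(read_alignment(tmp), "unequal length")

  writeLines(c(">a", "ACRT", ">b", "ACGT"), tmp)
  expect_error(read_alignment(tmp), "IUPAC")

  writeLines(c(">a", "ACGT", ">b", "ACGA"), tmp)
  expect_error(read_alignment(tmp, default_schema_915()), "schema")

  # lower case is accepted and uppercased
  writeLines(c(">a", "acgt", ">b", "acga"), tmp)
  expect_equal(read_alignment(tmp)$mat[1, ], c("A", "C", "G", "T"),
               ignore_attr = TRUE)
})

test_that("alignments round-trip through FASTA", {
  set.seed(3)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE),
                             collapse = ""))
  aln <- make_aln(seqs)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, tmp)
  back <- read_alignment(tmp)
  expect_identical(back$mat, aln$mat)
  expect_identical(back$ids, aln$ids)
})

test_that("a segregating multi-base deletion is recoded as one event", {
  rc <- 12660:12672
  aln <- make_aln(c("AAAAATTTAAAAA",
                    "AAAAA---AAAAA",
                    "AAAAATTTAAAAA"),
                  ref_coords = rc)
  rec <- recode_indel(aln, c(12665, 12667))
  expect_equal(aln_length(rec), 11L)  # three columns collapsed to one
  D <- pairwise_diff_counts(rec)
  expect_equal(D["s01", "s02"], 1)  # the indel counts once
  expect_equal(D["s01", "s03"], 0)
  # idempotent
  rec2 <- recode_indel(rec, c(12665, 12667))
  expect_identical(rec2, rec)
})

test_that("recoding is a no-op when no sequence carries the deletion", {
  rc <- 12660:12672
  aln <- make_aln(c("AAAAATTTAAAAA", "AAAAATTCAAAAA"), ref_coords = rc)
  rec <- recode_indel(aln, c(12665, 12667))
  expect_identical(rec$mat, aln$mat)
  expect_equal(aln_length(rec), 13L)
})

test_that("a partial gap inside the indel block is an error", {
  rc <- 12660:12672
  aln <- make_aln(c("AAAAATTTAAAAA", "AAAAAT--AAAAA"), ref_coords = rc)
  expect_error(recode_indel(aln, c(12665, 12667)), "s02")
})

test_that("genotype tables parse both layouts, missing codes and errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tFCA005\tFCA008\tFCA014",
               "i1\t146/150\t-9/-9\t100/100",
               "i2\t146/146\t120/124\t-9/-9"), tmp)
  gm <- read_genotypes(tmp)
  expect_equal(gm$loci, c("FCA005", "FCA008", "FCA014"))
  expect_equal(sort(c(gm$a1["i1", "FCA005"], gm$a2["i1", "FCA005"])),
               c(146L, 150L))
  expect_equal(sum(is.na(gm$a1)), 2L)

  # two-column layout, CSV
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,LocA,LocA,LocB,LocB",
               "i1,10,12,7,7",
               "i2,10,10,,"), tmp2)
  gm2 <- read_genotypes(tmp2)
  expect_equal(gm2$loci, c("LocA", "LocB"))
  expect_true(is.na(gm2$a1["i2", "LocB"]))

  # a locus with zero observed alleles is dropped with a warning
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tL1\tL2", "i1\t10/10\t-9/-9", "i2\t12/12\t-9/-9"), tmp3)
  expect_warning(gm3 <- read_genotypes(tmp3), "zero observed")
  expect_equal(gm3$loci, "L1")

  tmp4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tL1", "i1\t10/ab"), tmp4)
  expect_error(read_genotypes(tmp4), "non-integer")
})

test_that("genotype tables round-trip through the slash layout", {
  gm <- random_gm(6, 4, seed = 8)
  gm$a1[2, 3] <- gm$a2[2, 3] <- NA_integer_
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, tmp)
  back <- read_genotypes(tmp)
  expect_identical(back$a1, gm$a1)
  expect_identical(back$a2, gm$a2)
})

test_that("PHYLIP distance matrices are validated and round-trip", {
  z <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tmp <- withr::local_tempfile()
  write_distance_matrix(z, tmp)
  expect_equal(read_distance_matrix(tmp), z)

  set.seed(4)
  m <- matrix(runif(9), 3)
  m <- round((m + t(m)) / 2, 6); diag(m) <- 0
  dimnames(m) <- list(letters[1:3], letters[1:3])
  write_distance_matrix(m, tmp)
  expect_equal(read_distance_matrix(tmp), m)  # 6-decimal values: exact

  bad <- m; bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(write_distance_matrix(bad, tmp), "asymmetric")
  bad2 <- m; diag(bad2) <- 0.5
  expect_error(write_distance_matrix(bad2, tmp), "diagonal")
})

test_that("population maps reject duplicated samples", {
  tmp <- withr::local_tempfile()
  writeLines(c("s1\tX", "s2\tY"), tmp)
  pm <- read_popmap(tmp)
  expect_equal(pm, c(s1 = "X", s2 = "Y"))
  writeLines(c("s1\tX", "s1\tY"), tmp)
  expect_error(read_popmap(tmp), "more than once")
})
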