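#' Sequence alignment container
#'
#' A thin S3 container for an aligned set of haplotype-bearing sequences:
#' a character matrix (rows = samples, columns = sites) over
#' `{A,C,G,T,-,N}`, optionally annotated with per-column reference
#' coordinates and with a record of indel events that have been recoded to
#' single columns (see [recode_indel()]).
#'
#' @param ids character vector of sample identifiers.
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix with one row per sample.
#' @param ref_coords optional integer vector of per-column reference
#'   positions (1-based, e.g. GenBank numbering).
#' @return An object of class `SequenceAlignment` with elements `ids`,
#'   `mat` (character matrix), `ref_coords` (or NULL) and `indel_events`
#'   (data.frame of recoded blocks).
#' @export
new_alignment <- function(ids, seqs, ref_coords = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment format error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  mat <- toupper(mat)
  if (ncol(mat) == 0L) stop("alignment has zero length")
  if (length(ids) != nrow(mat)) stop("ids/seqs length mismatch")
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad) > 0)
    stop("unsupported characters in alignment (IUPAC ambiguity codes other ",
         "than N are rejected): ", paste(bad, collapse = " "))
  if (!is.null(ref_coords)) {
    ref_coords <- as.integer(ref_coords)
    if (length(ref_coords) != ncol(mat))
      stop("schema error: ref_coords length ", length(ref_coords),
           " does not match alignment length ", ncol(mat))
  }
  rownames(mat) <- ids
  structure(list(ids = as.character(ids), mat = mat,
                 ref_coords = ref_coords,
                 indel_events = data.frame(ref_start = integer(),
                                           ref_end = integer(),
                                           col = integer())),
            class = "SequenceAlignment")
}

#' @export
print.SequenceAlignment <- function(x, ...) {
  cat("SequenceAlignment:", length(x$ids), "sequences x", ncol(x$mat),
      "sites\n")
  if (!is.null(x$ref_coords))
    cat("  reference coordinates:", x$ref_coords[1], "..",
        x$ref_coords[length(x$ref_coords)], "\n")
  if (nrow(x$indel_events) > 0)
    cat("  recoded indel events:", nrow(x$indel_events), "\n")
  invisible(x)
}

#' Alignment length (number of sites)
#' @param aln a [SequenceAlignment].
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' Read an aligned FASTA file
#'
#' Reads a pre-aligned FASTA (case-insensitive; uppercased internally) and
#' optionally applies a concatenation schema annotating every column with
#' its reference coordinate. The schema's total length must match the
#' alignment length.
#'
#' @param path FASTA file.
#' @param schema optional [concat_schema()].
#' @return A [new_alignment()] object.
#' @export
read_alignment <- function(path, schema = NULL) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("alignment format error: empty FASTA")
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("alignment format error: records have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  mat <- toupper(as.character(as.matrix(dna)))
  ref <- NULL
  if (!is.null(schema)) {
    if (attr(schema, "total") != ncol(mat))
      stop("schema error: schema covers ", attr(schema, "total"),
           " columns but alignment has ", ncol(mat))
    ref <- schema_ref_coords(schema)
  }
  new_alignment(names(dna), mat, ref)
}

#' Write an alignment to FASTA
#' @param aln a [SequenceAlignment].
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2L * length(aln$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- apply(aln$mat, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Recode a multi-base indel as a single event
#'
#' A deletion spanning several adjacent columns is a single evolutionary
#' event; counting each gapped column as a difference would overweight it.
#' This replaces the block with one presence/absence column (the retained
#' column carries the first base of the block for 'present' sequences and
#' `-` for 'absent' ones) so downstream difference counts score the indel
#' as exactly one event. Recoding is idempotent: re-applying the same block
#' is a no-op.
#'
#' @param aln a [SequenceAlignment].
#' @param block length-2 integer vector `c(start, end)`: a reference-
#'   coordinate interval when the alignment has `ref_coords`, otherwise
#'   column indices.
#' @return The recoded [SequenceAlignment].
#' @export
recode_indel <- function(aln, block) {
  block <- as.integer(block)
  if (length(block) != 2L || block[2] < block[1]) stop("bad block")
  ev <- aln$indel_events
  if (nrow(ev) > 0 && any(ev$ref_start == block[1] & ev$ref_end == block[2]))
    return(aln)  # already recoded
  if (!is.null(aln$ref_coords)) {
    cols <- which(aln$ref_coords >= block[1] & aln$ref_coords <= block[2])
  } else {
    cols <- block[1]:block[2]
    if (max(cols) > ncol(aln$mat)) stop("block outside alignment")
  }
  if (length(cols) == 0L) stop("block covers no alignment columns")
  sub <- aln$mat[, cols, drop = FALSE]
  gapped <- sub == "-"
  n_gap <- rowSums(gapped)
  partial <- n_gap > 0 & n_gap < length(cols)
  if (any(partial))
    stop("indel ambiguity error: partial gap in block ", block[1], "-",
         block[2], " for sequence(s): ",
         paste(aln$ids[partial], collapse = ", "))
  if (!any(n_gap == length(cols))) {
    # no sequence carries the deletion: nothing to recode, bookkeeping only
    aln$indel_events <- rbind(aln$indel_events,
                              data.frame(ref_start = block[1],
                                         ref_end = block[2],
                                         col = NA_integer_))
    return(aln)
  }
  keep_col <- cols[1]
  state <- ifelse(n_gap == length(cols), "-", sub[, 1])
  # sequences fully deleted in the block keep "-"; present ones keep the
  # block's first base so the column remains an ordinary site otherwise
  mat <- aln$mat
  mat[, keep_col] <- state
  drop_cols <- cols[-1]
  if (length(drop_cols) > 0) {
    mat <- mat[, -drop_cols, drop = FALSE]
    if (!is.null(aln$ref_coords)) aln$ref_coords <- aln$ref_coords[-drop_cols]
  }
  aln$mat <- mat
  new_col <- if (is.null(aln$ref_coords)) keep_col else
    which(aln$ref_coords >= block[1] & aln$ref_coords <= block[2])[1]
  aln$indel_events <- rbind(aln$indel_events,
                            data.frame(ref_start = block[1],
                                       ref_end = block[2], col = new_col))
  aln
}

#' Population map
#'
#' Reads a two-column delimited file (`sample_id<TAB>population`, no
#' header) into a named character vector mapping sample to population.
#'
#' @param path file path.
#' @return Named character vector.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "", as.is = TRUE,
                           col.names = c("sample", "population"))
  if (nrow(tab) == 0) stop("empty population map")
  if (anyDuplicated(tab$sample))
    stop("sample(s) listed more than once in population map: ",
         paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  stats::setNames(as.character(tab$population), tab$sample)
}

#' @rdname read_popmap
#' @param popmap named character vector.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(data.frame(names(popmap), unname(popmap)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Microsatellite genotype container
#'
#' Diploid integer allele sizes per individual and locus. A genotype is an
#' unordered pair; a pair is either fully observed or fully missing (NA).
#'
#' @param individuals sample ids.
#' @param loci locus names.
#' @param a1,a2 integer matrices (individual x locus) of allele sizes; NA
#'   for missing.
#' @param units `"bp"` or `"repeats"`.
#' @param motif_length optional named integer vector (per locus) used to
#'   convert bp sizes to repeat units in size-based statistics.
#' @return Object of class `GenotypeMatrix`.
#' @export
new_genotypes <- function(individuals, loci, a1, a2, units = "repeats",
                          motif_length = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2)) || nrow(a1) != length(individuals) ||
      ncol(a1) != length(loci))
    stop("genotype matrix dimension mismatch")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing genotype(s): a pair must be fully present or fully ",
         "missing (first at individual ",
         individuals[which(half, arr.ind = TRUE)[1, 1]], ")")
  if (any(c(a1, a2) <= 0, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(list(individuals = as.character(individuals),
                 loci = as.character(loci), a1 = a1, a2 = a2,
                 units = units, motif_length = motif_length),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci (units:", x$units, ")\n")
  cat("  missing genotypes:", sum(is.na(x$a1)), "\n")
  invisible(x)
}

#' Read a diploid microsatellite genotype table
#'
#' Accepts a delimited text table (TSV or CSV, autodetected) with a header
#' row: first column the individual id, then either two columns per locus
#' (the locus name repeated) or one column per locus with `a/b` cells.
#' Missing genotypes are blank, `NA`, `-9` or `-9/-9`. Loci with zero
#' observed alleles are dropped with a warning.
#'
#' @param path file path.
#' @param units,motif_length passed to [new_genotypes()].
#' @return A `GenotypeMatrix`.
#' @export
read_genotypes <- function(path, units = "repeats", motif_length = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, as.is = TRUE,
                           check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(tab) < 2) stop("genotype table needs an id column plus loci")
  ids <- as.character(tab[[1]])
  nm <- colnames(tab)[-1]  # before subsetting: [.data.frame mangles dups
  body <- tab[, -1, drop = FALSE]
  two_col <- ncol(body) %% 2L == 0L &&
    all(nm[c(TRUE, FALSE)] == nm[c(FALSE, TRUE)])
  parse_int <- function(x, row, col) {
    out <- suppressWarnings(as.integer(x))
    bad <- !is.na(x) & is.na(out) & x != ""
    if (any(bad))
      stop("genotype parse error: non-integer allele '", x[which(bad)[1]],
           "' at row ", row[which(bad)[1]], ", column '", col, "'")
    out
  }
  if (two_col) {
    loci <- nm[c(TRUE, FALSE)]
    a1 <- sapply(seq_along(loci), function(j)
      parse_int(as.character(body[[2 * j - 1]]), seq_len(nrow(body)), loci[j]))
    a2 <- sapply(seq_along(loci), function(j)
      parse_int(as.character(body[[2 * j]]), seq_len(nrow(body)), loci[j]))
  } else {
    loci <- nm
    split2 <- function(cells, col) {
      parts <- strsplit(ifelse(is.na(cells), "NA/NA", cells), "/", fixed = TRUE)
      if (any(lengths(parts) != 2))
        stop("genotype parse error: expected 'a/b' cell in column '", col, "'")
      list(parse_int(vapply(parts, `[`, "", 1), seq_along(cells), col),
           parse_int(vapply(parts, `[`, "", 2), seq_along(cells), col))
    }
    cols <- lapply(seq_along(loci), function(j)
      split2(as.character(body[[j]]), loci[j]))
    a1 <- sapply(cols, `[[`, 1)
    a2 <- sapply(cols, `[[`, 2)
  }
  a1 <- matrix(as.integer(a1), nrow = length(ids))
  a2 <- matrix(as.integer(a2), nrow = length(ids))
  a1[a1 == -9L] <- NA_integer_; a2[a2 == -9L] <- NA_integer_
  # a pair with one side missing is treated as fully missing
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  empty <- colSums(!is.na(a1)) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " locus/loci with zero observed ",
            "alleles: ", paste(loci[empty], collapse = ", "))
    a1 <- a1[, !empty, drop = FALSE]; a2 <- a2[, !empty, drop = FALSE]
    loci <- loci[!empty]
  }
  new_genotypes(ids, loci, a1, a2, units = units,
                motif_length = motif_length)
}

#' @rdname read_genotypes
#' @param gm a `GenotypeMatrix`.
#' @export
write_genotypes <- function(gm, path) {
  cells <- matrix(paste0(ifelse(is.na(gm$a1), "-9", gm$a1), "/",
                         ifelse(is.na(gm$a2), "-9", gm$a2)),
                  nrow = length(gm$individuals),
                  dimnames = list(NULL, gm$loci))
  out <- data.frame(id = gm$individuals, cells, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a PHYLIP square distance matrix
#'
#' Fixed-point 6-decimal square matrix, the format consumed by classical
#' neighbor-joining tools. The matrix must be symmetric (to 1e-9) with a
#' zero diagonal.
#'
#' @param mat square numeric matrix with dimnames.
#' @param path output file.
#' @export
write_distance_matrix <- function(mat, path) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("distance matrix must be square")
  if (any(abs(mat - t(mat)) > 1e-9))
    stop("distance matrix asymmetric beyond 1e-9")
  if (any(abs(diag(mat)) > 1e-9))
    stop("distance matrix diagonal must be zero")
  nm <- rownames(mat)
  if (is.null(nm)) nm <- paste0("S", seq_len(nrow(mat)))
  nm10 <- formatC(substr(gsub("[[:space:]]", "_", nm), 1, 10),
                  width = -10)
  rows <- vapply(seq_len(nrow(mat)), function(i)
    paste0(nm10[i], paste(formatC(mat[i, ], format = "f", digits = 6),
                          collapse = " ")), "")
  writeLines(c(sprintf("%5d", nrow(mat)), rows), path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- lines[1 + seq_len(n)]
  nm <- trimws(substr(rows, 1, 10))
  vals <- lapply(rows, function(r)
    as.numeric(strsplit(trimws(substring(r, 11)), "[[:space:]]+")[[1]]))
  mat <- do.call(rbind, vals)
  dimnames(mat) <- list(nm, nm)
  mat
}
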