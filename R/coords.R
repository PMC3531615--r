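#' Reference-coordinate concatenation schemas
#'
#' Analyses of short, non-contiguous mtDNA fragments are usually run on a
#' concatenated alignment whose columns keep their original reference
#' coordinates (1-based, inclusive, in the numbering of the mitochondrial
#' reference sequence). A schema is an ordered set of reference intervals;
#' applying it to an alignment annotates every column with its reference
#' position.
#'
#' `concat_schema()` builds a schema from interval start/end vectors.
#' `default_schema_915()` is the five-block schema used throughout this
#' package's worked examples: the last 29 bp of tRNA-Leu (12628-12656),
#' partial MT-ND5 (12657-13087), partial cytochrome b (15940-16173) and two
#' control-region pieces (16333-16487, 16811-16876), totalling 915 columns.
#'
#' @param starts,ends integer vectors of 1-based inclusive interval bounds.
#' @return An object of class `concat_schema`: a data.frame with columns
#'   `start`, `end`, `length`, plus attribute `total` (column count).
#' @examples
#' sch <- default_schema_915()
#' attr(sch, "total")  # 915
#' @export
concat_schema <- function(starts, ends) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends) || length(starts) == 0)
    stop("starts and ends must be equal-length, non-empty")
  if (any(ends < starts)) stop("interval end before start")
  if (any(starts < 1L)) stop("coordinates are 1-based; start < 1")
  sch <- data.frame(start = starts, end = ends,
                    length = ends - starts + 1L)
  attr(sch, "total") <- sum(sch$length)
  class(sch) <- c("concat_schema", class(sch))
  sch
}

#' @rdname concat_schema
#' @export
default_schema_915 <- function() {
  concat_schema(c(12628L, 12657L, 15940L, 16333L, 16811L),
                c(12656L, 13087L, 16173L, 16487L, 16876L))
}

#' Expand a schema into per-column reference positions
#'
#' @param schema a `concat_schema`.
#' @return Integer vector of reference positions, one per alignment column,
#'   strictly increasing within each block.
#' @export
schema_ref_coords <- function(schema) {
  unlist(lapply(seq_len(nrow(schema)),
                function(i) schema$start[i]:schema$end[i]), use.names = FALSE)
}

#' Convert reference positions to alignment column indices
#'
#' Reference coordinates are 1-based inclusive; alignment columns are
#' 1-based. Internally, interval arithmetic uses 0-based half-open form in
#' one place only (this function), so conversions are property-tested once.
#'
#' @param ref_coords integer vector of per-column reference positions (as
#'   stored on a [SequenceAlignment]).
#' @param positions reference positions to look up.
#' @return Integer column indices; NA where a position is not covered.
#' @export
ref_to_col <- function(ref_coords, positions) {
  match(as.integer(positions), as.integer(ref_coords))
}

#' @rdname ref_to_col
#' @param cols alignment column indices to convert back.
#' @export
col_to_ref <- function(ref_coords, cols) {
  cols <- as.integer(cols)
  # 0-based half-open internally: column c covers [c-1, c)
  out <- rep(NA_integer_, length(cols))
  ok <- !is.na(cols) & cols >= 1L & cols <= length(ref_coords)
  out[ok] <- as.integer(ref_coords)[cols[ok]]
  out
}
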