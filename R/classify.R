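# Diagnostic-site haplogroup classifier for short (139-bp) mtDNA
# fragments. The informative positions (mitochondrial reference numbering)
# and the states fixed in, and exclusive to, each haplogroup follow the
# screened concatenated ND5/control-region fragment.

DIAG_POSITIONS <- c("12665-12667", "12679", "12698", "12707", "16448",
                    "16454", "16473", "16474", "16817", "16818", "16831",
                    "16854")

# diagnostic (fixed-and-exclusive) states
DIAG_RULES <- list(
  soemmeringii = list(`12665-12667` = "del", `12698` = "A", `16473` = "C"),
  venaticus    = list(`16448` = "T"),
  north_africa = list(`12707` = "G")
)

#' Classify a diagnostic mtDNA fragment into a haplogroup
#'
#' Applies the diagnostic-site rules for the 139-bp concatenated fragment:
#' a 3-bp deletion at 12665-12667, A at 12698 or C at 16473 is diagnostic
#' for the Northern-East African haplogroup (*soemmeringii*); T at 16448
#' for the Asiatic haplogroup (*venaticus*); G at 12707 for the North
#' African population. Fragments informative at one or more screened
#' positions but carrying no diagnostic state are called
#' `jubatus_raineyi` (the two sub-Saharan haplogroups are not separable by
#' fixed diagnostic states). Diagnostics supporting different haplogroups
#' raise a conflict error listing the offending sites.
#'
#' @param states named character vector of observed states. Names are the
#'   screened positions (`"12679"`, ..., plus `"12665-12667"` for the
#'   indel, whose state is `"del"`/`"-"` when deleted or the retained
#'   bases, e.g. `"ATC"`, when intact). Unreadable positions may be NA or
#'   simply absent.
#' @return A `haplogroup_call` list: `label` (one of `venaticus`,
#'   `soemmeringii`, `north_africa`, `jubatus_raineyi`, `no_call`),
#'   `supporting_sites` (data.frame of diagnostic position/state matches)
#'   and `n_informative_observed`.
#' @export
classify_haplogroup <- function(states) {
  states <- states[!is.na(states)]
  states <- toupper(trimws(states))
  states[states == "-" | states == "---"] <- "DEL"
  known <- intersect(names(states), DIAG_POSITIONS)
  if (length(known) == 0)
    return(structure(list(label = "no_call",
                          supporting_sites = data.frame(position = character(),
                                                        state = character()),
                          n_informative_observed = 0L),
                     class = "haplogroup_call"))
  hits <- data.frame(position = character(), state = character(),
                     label = character())
  for (lab in names(DIAG_RULES)) {
    for (pos in names(DIAG_RULES[[lab]])) {
      want <- toupper(DIAG_RULES[[lab]][[pos]])
      if (pos %in% names(states) && states[[pos]] == want)
        hits <- rbind(hits, data.frame(position = pos, state = want,
                                       label = lab))
    }
  }
  labs <- unique(hits$label)
  if (length(labs) > 1)
    stop("conflicting diagnostic states: ",
         paste(sprintf("%s@%s->%s", hits$state, hits$position, hits$label),
               collapse = ", "))
  label <- if (length(labs) == 1) labs else "jubatus_raineyi"
  structure(list(label = label,
                 supporting_sites = hits[, c("position", "state")],
                 n_informative_observed = length(known)),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat("haplogroup:", x$label, "(", x$n_informative_observed,
      "informative site(s) observed )\n")
  if (nrow(x$supporting_sites) > 0)
    cat("  supported by:",
        paste(sprintf("%s@%s", x$supporting_sites$state,
                      x$supporting_sites$position), collapse = ", "), "\n")
  invisible(x)
}

#' Classify every sequence of an annotated alignment
#'
#' Extracts the screened diagnostic positions from an alignment carrying
#' reference coordinates and classifies each sequence. The indel state is
#' read from a recoded indel column when present, else from the raw
#' columns.
#'
#' @param aln a [SequenceAlignment] with `ref_coords` covering (some of)
#'   the diagnostic positions.
#' @return data.frame with `id`, `haplogroup`, `n_informative`.
#' @export
classify_alignment <- function(aln) {
  if (is.null(aln$ref_coords))
    stop("classify_alignment needs reference coordinates")
  snp_pos <- setdiff(DIAG_POSITIONS, "12665-12667")
  cols <- ref_to_col(aln$ref_coords, as.integer(snp_pos))
  indel_cols <- which(aln$ref_coords >= 12665 & aln$ref_coords <= 12667)
  res <- lapply(seq_along(aln$ids), function(i) {
    st <- character(0)
    for (k in seq_along(snp_pos)) {
      if (!is.na(cols[k])) {
        v <- aln$mat[i, cols[k]]
        if (v != "N") st[snp_pos[k]] <- v
      }
    }
    if (length(indel_cols) > 0) {
      v <- aln$mat[i, indel_cols]
      if (!all(v == "N"))
        st["12665-12667"] <- if (any(v == "-")) "del" else
          paste(v, collapse = "")
    }
    classify_haplogroup(st)
  })
  data.frame(id = aln$ids,
             haplogroup = vapply(res, `[[`, "", "label"),
             n_informative = vapply(res, function(r)
               r$n_informative_observed, 0L))
}
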