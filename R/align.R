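encode_seq <- function(x, alphabet) {
  idx <- match(str_split(x, "")[[1]], alphabet)
  if (anyNA(idx))
    abort_bad_arg("sequence contains letters absent from the substitution matrix.")
  idx - 1L
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Exact local dynamic programming (Gotoh) under an affine gap model where a
#' gap of length L costs `gap_open + gap_extend * L` (the BLASTP default
#' parameterization with BLOSUM62, 11, 1).  Tie-breaking is deterministic:
#' the optimal cell with the smallest (query row, target column) wins, and
#' the traceback prefers diagonal over up (gap in target) over left (gap in
#' query).  An all-negative comparison returns the empty alignment with
#' score 0.
#'
#' @param query,target Non-empty amino-acid strings.
#' @param submat Substitution matrix with dimnames covering both sequences'
#'   letters; default [blosum62()] (X scored as the worst value of the
#'   canonical column).
#' @param gap_open,gap_extend Affine gap parameters (penalties, >= 0).
#' @return An object of class `phytasp_alignment`: a list with `score`,
#'   `query_span` and `target_span` (1-based inclusive; `c(0L, -1L)` for the
#'   empty alignment), and `pairs`, a two-column matrix of matched
#'   (query, target) positions.
#' @export
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")$score
local_align <- function(query, target, submat = blosum62(),
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(target))
    abort_bad_arg("`query` and `target` must be non-empty sequences.")
  alphabet <- rownames(submat)
  res <- sw_align_cpp(encode_seq(query, alphabet),
                      encode_seq(target, alphabet),
                      submat, gap_open, gap_extend)
  out <- list(score = res$score,
              query_span = c(res$query_start, res$query_end),
              target_span = c(res$target_start, res$target_end),
              pairs = res$pairs)
  colnames(out$pairs) <- c("query", "target")
  class(out) <- "phytasp_alignment"
  out
}

#' @export
print.phytasp_alignment <- function(x, ...) {
  cat(sprintf("<local alignment> score %g, query %d-%d, target %d-%d, %d matched positions\n",
              x$score, x$query_span[1], x$query_span[2],
              x$target_span[1], x$target_span[2], nrow(x$pairs)))
  invisible(x)
}

# Gapless self-alignment score of a sequence: sum of diagonal matrix entries.
self_score <- function(sequence, submat = blosum62()) {
  idx <- encode_seq(sequence, rownames(submat)) + 1L
  sum(submat[cbind(idx, idx)])
}

# Map a reference (query) position through the alignment; NA when the
# position falls in a gap or outside the aligned region.
map_position <- function(alignment, ref_pos) {
  hit <- alignment$pairs[alignment$pairs[, "query"] == ref_pos, "target"]
  if (length(hit) == 1L) hit else NA_integer_
}
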