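# Global and semi-global pairwise alignment with affine gaps, and the
# projection of an alignment onto query coordinates.  The DP core lives in
# src/align.cpp; the traceback tie-break is fixed (diagonal > up > left) so
# alignments are bit-reproducible across runs and platforms.

#' Alignment scoring scheme
#'
#' Affine gap model: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. The defaults (+5/-4/-10/-1,
#' EDNAFULL-like) penalize gaps strongly, appropriate for collinear operon
#' variants whose differences are almost entirely substitutions.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open,gap_extend Gap penalties (<= 0, `gap_open <= gap_extend`).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5L, mismatch = -4L,
                           gap_open = -10L, gap_extend = -1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match reward must be positive", call. = FALSE)
  if (mismatch >= 0L) stop("mismatch penalty must be negative", call. = FALSE)
  if (gap_open > 0L || gap_extend > 0L || gap_open > gap_extend) {
    stop("gap penalties must satisfy gap_open <= gap_extend <= 0",
         call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

new_alignment <- function(query_id, target_id, raw, denom_columns) {
  structure(list(
    query_id = query_id, target_id = target_id,
    aligned_query = raw$aligned_query, aligned_target = raw$aligned_target,
    score = raw$score,
    matches = raw$matches, columns = raw$columns,
    identity = if (denom_columns > 0L) raw$matches / denom_columns else NA_real_,
    t_start = raw$t_start, t_end = raw$t_end),
    class = "pairwise_alignment")
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' @param a,b Sequences (character strings or [annotated_operon()] objects);
#'   both non-empty.
#' @param scoring A [scoring_scheme()].
#' @return A `pairwise_alignment`: equal-length gapped strings
#'   `aligned_query`/`aligned_target`, the optimal `score`, and `identity` =
#'   matches / alignment columns (gap columns count as non-matches).
#' @export
#' @examples
#' align_global("ACGT", "ACGA")$identity  # 0.75
align_global <- function(a, b, scoring = scoring_scheme()) {
  qa <- as_seq(a, "query"); tb <- as_seq(b, "target")
  if (!nzchar(qa) || !nzchar(tb)) stop("empty sequence", call. = FALSE)
  raw <- .cpp_align(qa, tb, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend, "global")
  new_alignment(seq_label(a, "query"), seq_label(b, "target"), raw,
                raw$columns)
}

#' Semi-global alignment of a read against a reference
#'
#' End gaps are free on the reference only: the read is aligned in full and
#' the reference contributes a contiguous span (`t_start`..`t_end`, 1-based
#' inclusive). Identity is computed over the read's aligned span.
#'
#' @inheritParams align_global
#' @param read,ref Sequences; the read is typically shorter.
#' @return A `pairwise_alignment` with span coordinates on the reference.
#' @export
align_semi_global <- function(read, ref, scoring = scoring_scheme()) {
  qa <- as_seq(read, "read"); tb <- as_seq(ref, "ref")
  if (!nzchar(qa) || !nzchar(tb)) stop("empty sequence", call. = FALSE)
  raw <- .cpp_align(qa, tb, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend, "semiglobal")
  new_alignment(seq_label(read, "read"), seq_label(ref, "ref"), raw,
                raw$columns)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: score %d, identity %.3f\n",
              x$query_id, x$target_id, x$score, x$identity))
  w <- 60L
  n <- nchar(x$aligned_query)
  for (off in seq(1L, n, by = w)) {
    aq <- substr(x$aligned_query, off, min(off + w - 1L, n))
    at <- substr(x$aligned_target, off, min(off + w - 1L, n))
    cat(" q: ", aq, "\n t: ", at, "\n", sep = "")
  }
  invisible(x)
}

#' Write an alignment in a simple 3-line text format
#'
#' One header line (`query_id`, `target_id`, score, identity) followed by the
#' two gapped strings. A debugging aid.
#'
#' @param alignment A `pairwise_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  writeLines(c(sprintf("# %s\t%s\tscore=%d\tidentity=%.6f",
                       alignment$query_id, alignment$target_id,
                       alignment$score, alignment$identity),
               alignment$aligned_query, alignment$aligned_target), path)
  invisible(path)
}

#' Project an alignment onto query coordinates
#'
#' For every query position, the target symbol aligned to it (or `"-"` where
#' the query position sits opposite a gap). Columns gapped in the query
#' (target insertions) are dropped from the projection but counted.
#'
#' @param alignment A `pairwise_alignment`.
#' @return A `query_projection`: list with `symbols` (character vector, one
#'   per query position) and `insertions` (dropped target-insertion count).
#' @export
project_alignment <- function(alignment) {
  q <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1L]]
  t <- strsplit(alignment$aligned_target, "", fixed = TRUE)[[1L]]
  keep <- q != "-"
  structure(list(symbols = t[keep], insertions = sum(!keep)),
            class = "query_projection")
}
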