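#' Build an interval table
#'
#' Intervals are 0-based half-open on the forward strand, the single
#' coordinate convention used throughout the package.
#'
#' @param seq_id Character vector of sequence ids.
#' @param start,end Integer vectors; `0 <= start < end`.
#' @param strand `"+"` or `"-"` (recycled).
#' @return A validated interval data frame.
#' @export
intervals <- function(seq_id, start, end, strand = "+") {
  out <- data.frame(seq_id = as.character(seq_id),
                    start = as.integer(start), end = as.integer(end),
                    strand = rep_len(strand, length(seq_id)),
                    stringsAsFactors = FALSE)
  validate_intervals(out)
  out
}

validate_intervals <- function(iv) {
  if (nrow(iv) == 0) return(invisible(iv))
  if (any(iv$start < 0)) stop("interval start must be >= 0")
  if (any(iv$end <= iv$start)) stop("interval end must exceed start")
  if (!all(iv$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(iv)
}

#' Total length of a set-theoretic union of intervals
#'
#' The primitive behind per-pair overlap coverage: overlapping and duplicated
#' intervals are collapsed before summing. All intervals must lie on the same
#' sequence.
#'
#' @param iv An interval data frame (see [intervals()]); an empty table gives
#'   0.
#' @return Integer number of base pairs covered by the union.
#' @export
interval_union_length <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0L)
  if (length(unique(iv$seq_id)) > 1L) {
    stop("interval_union_length: intervals span multiple seq_ids")
  }
  reduced <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L,
                                              end = iv$end))
  sum(IRanges::width(reduced))
}

# union length of [start,end) pairs without the seq_id bookkeeping
union_length0 <- function(start, end) {
  if (length(start) == 0) return(0L)
  reduced <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(reduced))
}
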