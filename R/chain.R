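#' Chain alignment blocks by weighted longest increasing subset
#'
#' Self-alignments of a heterozygous assembly are fractional: an exact
#' aligner breaks at every divergent locus, so one homologous region shows
#' up as many small blocks. This dynamic program selects the maximum-weight
#' subset of blocks that is strictly increasing in both query and target
#' forward-strand coordinates (decreasing target for minus-strand pairs),
#' with weight = matched bases - clustering the fragments of one locus into
#' a single chain. Among equal-weight chains the one with the smaller total
#' junction gap is preferred, then the one whose first block starts earlier
#' on the query. Selected blocks are removed and the leftovers re-chained
#' until nothing remains or the best chain weighs less than
#' `min_chain_weight`; the primary chain is always emitted.
#'
#' @param blocks Alignment blocks for a single contig pair and strand.
#' @param min_chain_weight Stop re-chaining leftovers below this weight.
#' @return A list of chains, each a list with `query_id`, `target_id`,
#'   `strand`, `blocks` (ordered data frame), `total_matched` and
#'   `span_identity` (total matched bases over total per-block span).
#' @export
chain_lis <- function(blocks, min_chain_weight = 100) {
  if (nrow(blocks) == 0) return(list())
  if (length(unique(blocks$query_id)) > 1 ||
      length(unique(blocks$target_id)) > 1 ||
      length(unique(blocks$strand)) > 1) {
    stop("chain_lis expects blocks from a single contig pair and strand")
  }
  remaining <- blocks
  chains <- list()
  repeat {
    if (nrow(remaining) == 0) break
    sel <- lis_select(remaining)
    chain <- make_chain(remaining[sel$idx, , drop = FALSE])
    if (length(chains) > 0 && sel$weight < min_chain_weight) break
    chains[[length(chains) + 1L]] <- chain
    remaining <- remaining[-sel$idx, , drop = FALSE]
    if (sel$weight < min_chain_weight) break
  }
  chains
}

# weighted-LIS dynamic program over one pair/strand block set; returns the
# selected row indices (in chain order) and the chain weight
lis_select <- function(b) {
  ord <- order(b$q_start, b$t_start)
  b <- b[ord, , drop = FALSE]
  n <- nrow(b)
  minus <- b$strand[1] == "-"
  w <- b$matched_bases
  best_w <- w                 # best chain weight ending at i
  best_gap <- numeric(n)      # its total junction gap
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      ok_q <- b$q_start[j] >= b$q_end[i]
      ok_t <- if (minus) b$t_end[j] <= b$t_start[i] else
                         b$t_start[j] >= b$t_end[i]
      if (!ok_q || !ok_t) next
      gap_t <- if (minus) b$t_start[i] - b$t_end[j] else
                          b$t_start[j] - b$t_end[i]
      cand_w <- best_w[i] + w[j]
      cand_gap <- best_gap[i] + (b$q_start[j] - b$q_end[i]) + gap_t
      if (cand_w > best_w[j] ||
          (cand_w == best_w[j] && cand_gap < best_gap[j])) {
        best_w[j] <- cand_w
        best_gap[j] <- cand_gap
        prev[j] <- i
      }
    }
  }
  # pick the best chain end: max weight, then min gap, then earliest start
  endi <- which(best_w == max(best_w))
  if (length(endi) > 1) endi <- endi[best_gap[endi] == min(best_gap[endi])]
  endi <- endi[1]
  path <- integer()
  i <- endi
  while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
  list(idx = ord[path], weight = max(best_w))
}

make_chain <- function(b) {
  b <- b[order(b$q_start), , drop = FALSE]
  rownames(b) <- NULL
  span <- pmax(b$q_end - b$q_start, b$t_end - b$t_start)
  list(query_id = b$query_id[1], target_id = b$target_id[1],
       strand = b$strand[1], blocks = b,
       total_matched = sum(b$matched_bases),
       span_identity = sum(b$matched_bases) / sum(span))
}

#' Merge adjacent blocks of a chain across small gaps
#'
#' Consecutive chained blocks whose gaps on both sequences are at most
#' `max_gap` are fused into one block spanning both; matched bases are
#' summed (bridged gap bases are not matched) and the fused block's identity
#' is the matched-weighted mean of its constituents. Where two consecutive
#' blocks overlap on the query, only the higher-score block contributes (the
#' repeat-alignment filter applied before merging). The chain keeps its
#' pre-merge `span_identity`: identity measures accuracy within aligned
#' segments, while the bridged gaps are accounted by coverage.
#'
#' @param chain A chain from [chain_lis()].
#' @param max_gap Maximum bridged gap in bp on each sequence.
#' @return The chain with merged blocks.
#' @export
merge_adjacent_blocks <- function(chain, max_gap = 500L) {
  b <- chain$blocks
  if (nrow(b) <= 1) return(chain)
  minus <- chain$strand == "-"

  # repeat filter: among consecutive blocks overlapping the same query span,
  # keep the higher score
  keep <- rep(TRUE, nrow(b))
  last <- 1L
  for (j in 2:nrow(b)) {
    if (b$q_start[j] < b$q_end[last]) {
      if (b$score[j] > b$score[last]) { keep[last] <- FALSE; last <- j }
      else keep[j] <- FALSE
    } else {
      last <- j
    }
  }
  b <- b[keep, , drop = FALSE]

  merged <- b[1, , drop = FALSE]
  for (j in seq_len(nrow(b) - 1L) + 1L) {
    cur <- merged[nrow(merged), ]
    gap_q <- b$q_start[j] - cur$q_end
    gap_t <- if (minus) cur$t_start - b$t_end[j] else b$t_start[j] - cur$t_end
    if (gap_q <= max_gap && gap_t <= max_gap) {
      wsum <- cur$matched_bases + b$matched_bases[j]
      cur$identity <- (cur$identity * cur$matched_bases +
                         b$identity[j] * b$matched_bases[j]) / wsum
      cur$q_end <- b$q_end[j]
      cur$t_start <- min(cur$t_start, b$t_start[j])
      cur$t_end <- max(cur$t_end, b$t_end[j])
      cur$matched_bases <- wsum
      cur$score <- cur$score + b$score[j]
      merged[nrow(merged), ] <- cur
    } else {
      merged <- rbind(merged, b[j, , drop = FALSE])
    }
  }
  rownames(merged) <- NULL
  chain$blocks <- merged
  chain$total_matched <- sum(merged$matched_bases)
  chain
}
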