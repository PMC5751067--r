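#' Anchor parameters for the internal self-aligner
#'
#' @param anchor_k Anchor k-mer length (>= 11).
#' @param max_anchor_occurrence Anchors occurring more often than this in
#'   the whole assembly are dropped as repeats (the stand-in for a
#'   reference-unique seeding mode).
#' @param min_block_len Blocks spanning fewer bases are dropped.
#' @return A list of class `anchor_params`.
#' @export
anchor_params <- function(anchor_k = 21L, max_anchor_occurrence = 10L,
                          min_block_len = 100L) {
  if (anchor_k < 11) stop("anchor_k must be >= 11")
  if (max_anchor_occurrence < 2) stop("max_anchor_occurrence must be >= 2")
  if (min_block_len < 1) stop("min_block_len must be positive")
  structure(list(anchor_k = as.integer(anchor_k),
                 max_anchor_occurrence = as.integer(max_anchor_occurrence),
                 min_block_len = as.integer(min_block_len)),
            class = "anchor_params")
}

#' Index the anchor k-mers of an assembly
#'
#' Maps every canonical `anchor_k`-mer occurring at most
#' `max_anchor_occurrence` times to its positions. Intended for inspection
#' and small inputs; [anchor_matches()] builds its index internally in
#' compiled code.
#'
#' @param contigs Sequences (any container accepted by the package).
#' @param params An [anchor_params()] list.
#' @return A list of class `anchor_index` with the parameters and a
#'   `positions` data frame (`kmer`, `contig_id`, `pos`, `strand`).
#' @export
build_anchor_index <- function(contigs, params = anchor_params()) {
  seqs <- as_sequences(contigs)
  if (length(seqs) == 0) stop("contig list is empty")
  k <- params$anchor_k
  tabs <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    fwd <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", fwd, fixed = TRUE)
    if (!any(ok)) return(NULL)
    fwd <- fwd[ok]
    rev <- revcomp(fwd)
    canon <- ifelse(fwd <= rev, fwd, rev)
    data.frame(kmer = canon, contig_id = names(seqs)[i],
               pos = starts[ok] - 1L,
               strand = ifelse(fwd <= rev, "+", "-"),
               stringsAsFactors = FALSE)
  })
  pos <- do.call(rbind, tabs)
  if (is.null(pos)) {
    pos <- data.frame(kmer = character(), contig_id = character(),
                      pos = integer(), strand = character())
  }
  occ <- table(pos$kmer)
  keep <- occ[pos$kmer] <= params$max_anchor_occurrence
  structure(list(params = params, positions = pos[keep, , drop = FALSE]),
            class = "anchor_index")
}

#' Whole-assembly self-alignment with exact anchors
#'
#' The internal substitute for an external whole-genome self-aligner:
#' canonical `anchor_k`-mers shared between two contigs are collapsed into
#' alignment blocks wherever they form maximal runs of consecutive
#' co-diagonal positions. Blocks are exact matches, so heterozygous
#' divergence shows up as breaks between blocks - exactly what the chaining
#' stage ([chain_lis()] plus [merge_adjacent_blocks()]) is designed to
#' bridge. Matches of a contig against itself are not emitted.
#'
#' @param contigs Sequences (any container accepted by the package).
#' @param params An [anchor_params()] list.
#' @return An alignment-block data frame with `source = "internal"` and
#'   identity 1 (the blocks are exact).
#' @export
anchor_matches <- function(contigs, params = anchor_params()) {
  seqs <- as_sequences(contigs)
  if (length(seqs) == 0) stop("contig list is empty")
  raw <- anchor_blocks_cpp(unname(seqs), params$anchor_k,
                           params$max_anchor_occurrence,
                           params$min_block_len)
  if (nrow(raw) == 0) return(alignment_blocks())
  alignment_blocks(query_id = names(seqs)[raw$query],
                   target_id = names(seqs)[raw$target],
                   q_start = raw$q_start, q_end = raw$q_end,
                   t_start = raw$t_start, t_end = raw$t_end,
                   strand = raw$strand,
                   matched_bases = raw$q_end - raw$q_start,
                   identity = 1,
                   score = raw$q_end - raw$q_start,
                   source = "internal",
                   q_len = nchar(seqs)[raw$query],
                   t_len = nchar(seqs)[raw$target])
}
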