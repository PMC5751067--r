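#' Summarise overlap coverage for one contig pair
#'
#' Projects the chained alignments of one contig pair onto the shorter
#' contig and reports which fraction of it is covered, together with a
#' matched-bases-weighted mean identity over the contributing chains. Each
#' chain is one clustered "larger match": its span from first to last block
#' counts as covered, because the whole point of chaining is that
#' heterozygous breaks inside a co-linear run belong to one homologous
#' region. This pair summary is the direct input of the 80% removal rule.
#'
#' @param chains A list of chains (both strands) for one contig pair.
#' @param lengths Named vector with the two contig lengths.
#' @return A one-row data frame with `short_id`, `long_id`, `short_len`,
#'   `long_len`, `covered_bp`, `coverage_fraction` and `identity`.
#' @export
pair_coverage <- function(chains, lengths) {
  if (length(lengths) != 2 || is.null(names(lengths))) {
    stop("lengths must be a named vector of the two contig lengths")
  }
  ids <- names(lengths)
  short_id <- ids[order(lengths, ids)][1]
  long_id <- setdiff(ids, short_id)
  short_len <- as.numeric(lengths[short_id])
  long_len <- as.numeric(lengths[long_id])

  starts <- integer(); ends <- integer()
  w <- numeric(); ident <- numeric()
  for (ch in chains) {
    if (!setequal(c(ch$query_id, ch$target_id), ids)) {
      stop("chain does not belong to this contig pair")
    }
    b <- ch$blocks
    if (ch$query_id == short_id) {
      starts <- c(starts, min(b$q_start)); ends <- c(ends, max(b$q_end))
    } else {
      starts <- c(starts, min(b$t_start)); ends <- c(ends, max(b$t_end))
    }
    w <- c(w, ch$total_matched)
    ident <- c(ident, ch$span_identity)
  }
  if (length(ends) > 0 && max(ends) > short_len) {
    stop("chain coordinates exceed the short contig length")
  }
  covered <- union_length0(starts, pmin(ends, short_len))
  data.frame(short_id = short_id, long_id = long_id,
             short_len = short_len, long_len = long_len,
             covered_bp = as.numeric(covered),
             coverage_fraction = covered / short_len,
             identity = if (length(w)) weighted.mean(ident, w) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Remove redundant heterozygous contigs
#'
#' The core purge: contig pairs are processed in decreasing order of the
#' long contig's length, and the short contig is discarded whenever the
#' covered fraction of its length reaches `coverage_removal_threshold`
#' (default 80%) and its coverer has not itself been removed earlier in the
#' pass (so a removed contig can never cause further removals, and both
#' haplotypes of a region cannot be lost). Removals whose pair identity
#' falls below `min_restore_identity` are auto-restored - the mechanised
#' form of reviewing each removal's dot plot - and an operator-supplied
#' restore list can re-add contigs by id. Each effective removal can export
#' a TSV dot plot of block endpoints for manual review.
#'
#' @param contigs Sequences (any container accepted by the package).
#' @param summaries Pair summaries from [pair_coverage()], row-bound.
#' @param cfg A [pipeline_config()].
#' @param restore_ids Contig ids to restore after the pass.
#' @param chains Optional list of chain lists keyed by `"short|long"` pair
#'   id, used for dot-plot export.
#' @param dotplot_dir Directory for per-removal dot-plot TSVs (created if
#'   needed); `NULL` disables export.
#' @return A list with `kept` (the retained sequences) and `decisions`, a
#'   data frame with one row per removal decision (`removed_id`, `kept_id`,
#'   `coverage_fraction`, `identity`, `restored`, `reason`).
#' @export
purge_assembly <- function(contigs, summaries, cfg = pipeline_config(),
                           restore_ids = character(), chains = NULL,
                           dotplot_dir = NULL) {
  seqs <- as_sequences(contigs)
  decisions <- data.frame(removed_id = character(), kept_id = character(),
                          coverage_fraction = numeric(),
                          identity = numeric(), restored = logical(),
                          reason = character(), stringsAsFactors = FALSE)
  removed <- character()
  if (!is.null(summaries) && nrow(summaries) > 0) {
    s <- summaries[order(-summaries$long_len, summaries$long_id,
                         summaries$short_id), , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      row <- s[i, ]
      if (row$long_id %in% removed || row$short_id %in% removed) next
      if (row$coverage_fraction < cfg$coverage_removal_threshold) next
      poor <- is.na(row$identity) || row$identity < cfg$min_restore_identity
      if (!poor) removed <- c(removed, row$short_id)
      decisions <- rbind(decisions, data.frame(
        removed_id = row$short_id, kept_id = row$long_id,
        coverage_fraction = row$coverage_fraction,
        identity = row$identity, restored = poor,
        reason = if (poor) "restored_low_identity" else
                           "heterozygous_duplicate",
        stringsAsFactors = FALSE))
      if (!poor && !is.null(dotplot_dir)) {
        export_dotplot(chains, row$short_id, row$long_id, dotplot_dir)
      }
    }
  }
  # operator restore list
  for (id in restore_ids) {
    hit <- which(decisions$removed_id == id & !decisions$restored)
    if (length(hit) == 0) {
      warning("restore list id never removed: ", id)
      next
    }
    decisions$restored[hit] <- TRUE
    decisions$reason[hit] <- "restored_by_operator"
    removed <- setdiff(removed, id)
  }
  list(kept = seqs[!(names(seqs) %in% removed)], decisions = decisions)
}

export_dotplot <- function(chains, short_id, long_id, dir) {
  if (is.null(chains)) return(invisible(NULL))
  key <- paste(sort(c(short_id, long_id)), collapse = "|")
  ch <- chains[[key]]
  if (is.null(ch)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  b <- do.call(rbind, lapply(ch, function(x) x$blocks))
  path <- file.path(dir, paste0(short_id, "_vs_", long_id, ".tsv"))
  write.table(b[, c("query_id", "target_id", "q_start", "q_end",
                    "t_start", "t_end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag mitochondrial contigs
#'
#' A contig is mitochondrial when at least `mito_coverage_threshold`
#' (default 80%) of its length is covered by alignments to mitochondrial
#' references with E-value below `mito_evalue_max` (default 1e-5).
#'
#' @param contig_hits Alignment blocks of assembly contigs (queries) against
#'   mitochondrial references; every block must carry an E-value.
#' @param contig_lengths Named vector of contig lengths.
#' @param cfg A [pipeline_config()].
#' @return Character vector of flagged contig ids.
#' @export
filter_mitochondrial <- function(contig_hits, contig_lengths,
                                 cfg = pipeline_config()) {
  if (nrow(contig_hits) == 0) return(character())
  if (anyNA(contig_hits$evalue)) {
    stop("block ", which(is.na(contig_hits$evalue))[1],
         " has no E-value; mitochondrial filtering needs blast6-style hits")
  }
  hits <- contig_hits[contig_hits$evalue < cfg$mito_evalue_max, , drop = FALSE]
  flagged <- character()
  for (id in unique(hits$query_id)) {
    if (!id %in% names(contig_lengths)) {
      stop("no length known for contig ", id)
    }
    h <- hits[hits$query_id == id, ]
    frac <- union_length0(h$q_start, h$q_end) / contig_lengths[[id]]
    if (frac >= cfg$mito_coverage_threshold) flagged <- c(flagged, id)
  }
  flagged
}

#' Screen contigs on the taxon-annotated GC-coverage (blob) plot
#'
#' A contig is discarded when its read coverage falls below
#' `blob_coverage_min`, or when its best database hit is outside the target
#' clade and there is neither transcript evidence nor a conserved
#' single-copy orthologue on it. Contigs with no best hit are treated as
#' in-clade.
#'
#' @param annotations Data frame with columns `contig_id`, `read_coverage`,
#'   `best_hit_taxon` (`NA` for none), `has_transcript_evidence`,
#'   `has_busco_gene`.
#' @param cfg A [pipeline_config()].
#' @param target_clade Clade name counted as "self".
#' @return A data frame with `contig_id`, `keep` and `rule`
#'   (`low_coverage`, `foreign_no_evidence` or `none`).
#' @export
filter_contaminants <- function(annotations, cfg = pipeline_config(),
                                target_clade = "Arthropoda") {
  a <- annotations
  foreign <- !is.na(a$best_hit_taxon) & a$best_hit_taxon != target_clade
  low <- a$read_coverage < cfg$blob_coverage_min
  no_ev <- !a$has_transcript_evidence & !a$has_busco_gene
  discard_foreign <- foreign & no_ev
  rule <- ifelse(low, "low_coverage",
                 ifelse(discard_foreign, "foreign_no_evidence", "none"))
  data.frame(contig_id = a$contig_id, keep = !(low | discard_foreign),
             rule = rule, stringsAsFactors = FALSE)
}

#' Run the whole purge pipeline on an assembly
#'
#' Convenience orchestration: self-align, pool optional external block
#' tables, chain per pair and strand, merge across small gaps, summarise
#' pair coverage, apply the removal/restore rules, then the mitochondrial
#' and contamination screens.
#'
#' @param contigs Sequences (any container accepted by the package).
#' @param cfg A [pipeline_config()].
#' @param params [anchor_params()] for the internal aligner.
#' @param extra_blocks Optional alignment blocks from external aligners,
#'   pooled with the internal ones before chaining.
#' @param mito_hits Optional blast6-style hits against mitochondrial
#'   references.
#' @param annotations Optional contig annotations for
#'   [filter_contaminants()].
#' @param restore_ids Operator restore list.
#' @param dotplot_dir Optional directory for removal dot plots.
#' @return A list with `kept`, `decisions`, `summaries`, `chains`,
#'   `mito_ids` and `contaminant_verdicts`.
#' @export
purge_pipeline <- function(contigs, cfg = pipeline_config(),
                           params = anchor_params(anchor_k = cfg$anchor_k),
                           extra_blocks = NULL, mito_hits = NULL,
                           annotations = NULL, restore_ids = character(),
                           dotplot_dir = NULL) {
  seqs <- as_sequences(contigs)
  lens <- setNames(nchar(seqs), names(seqs))
  blocks <- anchor_matches(seqs, params)
  if (!is.null(extra_blocks) && nrow(extra_blocks) > 0) {
    common <- intersect(names(blocks), names(extra_blocks))
    blocks <- rbind(blocks[common], extra_blocks[common])
  }

  chains_by_pair <- list()
  summaries <- NULL
  if (nrow(blocks) > 0) {
    first <- blocks$query_id <= blocks$target_id
    pair_key <- paste(ifelse(first, blocks$query_id, blocks$target_id),
                      ifelse(first, blocks$target_id, blocks$query_id),
                      sep = "|")
    for (key in unique(pair_key)) {
      sub <- blocks[pair_key == key, , drop = FALSE]
      chains <- list()
      for (ori in split(sub, paste(sub$query_id, sub$strand))) {
        cl <- chain_lis(ori, min_chain_weight = params$min_block_len)
        cl <- lapply(cl, merge_adjacent_blocks, max_gap = cfg$max_chain_gap)
        chains <- c(chains, cl)
      }
      chains_by_pair[[key]] <- chains
      ids <- strsplit(key, "|", fixed = TRUE)[[1]]
      summaries <- rbind(summaries, pair_coverage(chains, lens[ids]))
    }
  }

  purged <- purge_assembly(seqs, summaries, cfg, restore_ids = restore_ids,
                           chains = chains_by_pair, dotplot_dir = dotplot_dir)
  kept <- purged$kept

  mito_ids <- character()
  if (!is.null(mito_hits) && nrow(mito_hits) > 0) {
    mito_ids <- filter_mitochondrial(mito_hits, lens, cfg)
    kept <- kept[!(names(kept) %in% mito_ids)]
  }
  verdicts <- NULL
  if (!is.null(annotations)) {
    verdicts <- filter_contaminants(annotations, cfg)
    drop <- verdicts$contig_id[!verdicts$keep]
    kept <- kept[!(names(kept) %in% drop)]
  }
  list(kept = kept, decisions = purged$decisions, summaries = summaries,
       chains = chains_by_pair, mito_ids = mito_ids,
       contaminant_verdicts = verdicts)
}
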