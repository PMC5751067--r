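#' Pipeline configuration
#'
#' Collects every tunable threshold of the curation pipeline with the
#' defaults used throughout: the 80% overlap-coverage removal rule, the 0.90
#' identity floor below which a removal is auto-restored, the mitochondrial
#' rule (80% of the contig aligned at E-value < 1e-5), the blob-plot
#' coverage floor of 10, MISA-style SSR minimum unit counts, and the 2 kb /
#' 200 bp marker flank parameters.
#'
#' @param kmer_size k-mer length for spectrum analysis.
#' @param error_multiplicity_max Multiplicities up to this value count as
#'   sequencing-error k-mers in the genome-size estimator.
#' @param coverage_removal_threshold Fraction of a short contig that must be
#'   covered by a longer one before the short contig is discarded.
#' @param min_restore_identity Removals with pair identity below this value
#'   are restored (the mechanised dot-plot review).
#' @param mito_coverage_threshold,mito_evalue_max Mitochondrial filter rule.
#' @param blob_coverage_min Read-coverage floor on the blob plot.
#' @param max_chain_gap Maximum gap (bp, on both sequences) bridged when
#'   merging adjacent chained blocks.
#' @param anchor_k Anchor k-mer length for the internal self-aligner.
#' @param ssr_min_units Named integer vector mapping unit length (1-7) to the
#'   minimum number of repeat units.
#' @param compound_max_interruption Maximum spacer (bp) between perfect SSRs
#'   fused into a compound locus.
#' @param marker_flank_exclusion Window (bp) around a marker candidate that
#'   must be free of other SSRs.
#' @param marker_flank_len Flank length (bp) that must map uniquely.
#' @param rng_seed Seed recorded for reproducibility.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(kmer_size = 17L,
                            error_multiplicity_max = 1L,
                            coverage_removal_threshold = 0.80,
                            min_restore_identity = 0.90,
                            mito_coverage_threshold = 0.80,
                            mito_evalue_max = 1e-5,
                            blob_coverage_min = 10,
                            max_chain_gap = 500L,
                            anchor_k = 21L,
                            ssr_min_units = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                              `4` = 5L, `5` = 5L, `6` = 5L,
                                              `7` = 5L),
                            compound_max_interruption = 100L,
                            marker_flank_exclusion = 2000L,
                            marker_flank_len = 200L,
                            rng_seed = 1L) {
  cfg <- list(kmer_size = as.integer(kmer_size),
              error_multiplicity_max = as.integer(error_multiplicity_max),
              coverage_removal_threshold = coverage_removal_threshold,
              min_restore_identity = min_restore_identity,
              mito_coverage_threshold = mito_coverage_threshold,
              mito_evalue_max = mito_evalue_max,
              blob_coverage_min = blob_coverage_min,
              max_chain_gap = as.integer(max_chain_gap),
              anchor_k = as.integer(anchor_k),
              ssr_min_units = ssr_min_units,
              compound_max_interruption = as.integer(compound_max_interruption),
              marker_flank_exclusion = as.integer(marker_flank_exclusion),
              marker_flank_len = as.integer(marker_flank_len),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  frac <- c("coverage_removal_threshold", "min_restore_identity",
            "mito_coverage_threshold")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$kmer_size < 1) stop("kmer_size must be positive")
  if (cfg$mito_evalue_max < 0) stop("mito_evalue_max must be >= 0")
  if (cfg$anchor_k < 11) stop("anchor_k must be >= 11")
  if (is.null(names(cfg$ssr_min_units)) ||
      !all(names(cfg$ssr_min_units) == as.character(seq_along(cfg$ssr_min_units)))) {
    stop("ssr_min_units must be named 1..max unit length")
  }
  invisible(cfg)
}

#' Write or read a pipeline configuration as a flat key:value file
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  vals <- vapply(names(unclass(cfg)), function(k) {
    v <- cfg[[k]]
    if (k == "ssr_min_units") {
      paste(sprintf("%s:%d", names(v), v), collapse = ",")
    } else {
      format(v, scientific = TRUE, trim = TRUE)
    }
  }, "")
  writeLines(sprintf("%s: %s", names(vals), vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  args <- list()
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[i])
    if (k == "ssr_min_units") {
      parts <- strsplit(strsplit(v, ",")[[1]], ":")
      mu <- vapply(parts, function(p) as.integer(p[2]), 1L)
      names(mu) <- vapply(parts, function(p) trimws(p[1]), "")
      args[[k]] <- mu
    } else {
      args[[k]] <- as.numeric(v)
    }
  }
  do.call(pipeline_config, args)
}
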