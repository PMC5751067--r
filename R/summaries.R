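#' Assembly summary statistics
#'
#' N50/N90 conventions: with contigs sorted by decreasing length, the N50
#' length is the length of the contig at which the cumulative length first
#' reaches 50% of the assembly total, and the N50 count is that contig's
#' 1-based rank; N90 analogously at 90%. GC is computed over A/C/G/T bases
#' only (N excluded).
#'
#' @param contigs Sequences (any container accepted by the package).
#' @return A list of class `assembly_stats` with `n_contigs`, `total_len`,
#'   `mean_len`, `n50_len`, `n50_count`, `n90_len`, `n90_count`, `longest`
#'   and `gc_percent`.
#' @export
assembly_stats <- function(contigs) {
  seqs <- as_sequences(contigs)
  if (length(seqs) == 0) stop("assembly_stats needs at least one contig")
  lens <- sort(unname(nchar(seqs)), decreasing = TRUE)
  total <- sum(lens)
  cum <- cumsum(lens)
  i50 <- which(cum >= 0.5 * total)[1]
  i90 <- which(cum >= 0.9 * total)[1]
  comp <- base_composition(seqs)
  gc <- 100 * (comp["G"] + comp["C"]) / sum(comp[c("A", "C", "G", "T")])
  structure(list(n_contigs = length(lens), total_len = total,
                 mean_len = total / length(lens),
                 n50_len = lens[i50], n50_count = i50,
                 n90_len = lens[i90], n90_count = i90,
                 longest = lens[1],
                 gc_percent = round_half_up(unname(gc), 2)),
            class = "assembly_stats")
}

base_composition <- function(seqs) {
  m <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(clean_dna(unname(seqs))), collapse = TRUE)
  counts <- setNames(numeric(4), c("A", "C", "G", "T"))
  for (b in names(counts)) counts[b] <- m[[b]]
  counts
}

#' @export
print.assembly_stats <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat("Assembly statistics\n")
  cat(sprintf("  contigs: %s  total: %s bp  mean: %s bp\n",
              fmt(x$n_contigs), fmt(x$total_len), fmt(round(x$mean_len))))
  cat(sprintf("  N50: %s bp (rank %d)  N90: %s bp (rank %d)\n",
              fmt(x$n50_len), x$n50_count, fmt(x$n90_len), x$n90_count))
  cat(sprintf("  longest: %s bp  GC: %.2f%%\n", fmt(x$longest), x$gc_percent))
  invisible(x)
}

#' Summarise repeat content by class
#'
#' Per repeat class, the occupied length is the union of its intervals;
#' classes are assumed disjoint (RepeatMasker-style precedence applied
#' upstream), so the total is the sum over classes and overlap between
#' classes only warns. The transposable-element fraction is the share of
#' the DNA/LINE/SINE/LTR classes in all repeat-occupied bases.
#'
#' @param mask_by_class Named list mapping class name to an interval data
#'   frame, or a named numeric vector of pre-computed occupied lengths (in
#'   which case element counts are `NA`). A `Total` entry, when present,
#'   supplies the union-based total occupied length directly (RepeatMasker
#'   summaries report a non-redundant total that can be smaller than the
#'   per-class sum when classes overlap).
#' @param assembly_len Assembly length in bp.
#' @param element_counts Optional named vector of element counts per class.
#' @return A list with `table` (class, element_count, occupied_bp,
#'   percent_of_genome), `total_occupied`, `total_percent` and
#'   `te_fraction_of_repeats` (percent, 2 decimals, half-up).
#' @export
repeat_summary <- function(mask_by_class, assembly_len,
                           element_counts = NULL) {
  cls <- names(mask_by_class)
  if (is.null(cls)) stop("mask_by_class must be named by repeat class")
  stated_total <- NA_real_
  if ("Total" %in% cls) {
    stated_total <- if (is.numeric(mask_by_class)) {
      as.numeric(mask_by_class[["Total"]])
    } else {
      sum(vapply(split(mask_by_class[["Total"]],
                       mask_by_class[["Total"]]$seq_id),
                 interval_union_length, 0))
    }
    mask_by_class <- mask_by_class[cls != "Total"]
    cls <- names(mask_by_class)
  }
  if (is.numeric(mask_by_class)) {
    occupied <- as.numeric(mask_by_class)
    counts <- rep(NA_integer_, length(cls))
  } else {
    occupied <- vapply(mask_by_class, function(iv) {
      if (is.null(iv) || nrow(iv) == 0) return(0)
      if (any(iv$end > assembly_len)) {
        stop("repeat interval extends beyond the assembly length")
      }
      as.numeric(sum(vapply(split(iv, iv$seq_id), interval_union_length, 0)))
    }, 0)
    counts <- vapply(mask_by_class, nrow, 0L)
    all_iv <- do.call(rbind, mask_by_class)
    union_all <- sum(vapply(split(all_iv, all_iv$seq_id),
                            interval_union_length, 0))
    if (union_all < sum(occupied)) {
      warning("repeat classes overlap; total uses per-class sums")
    }
  }
  if (!is.null(element_counts)) counts <- as.integer(element_counts[cls])
  total <- if (is.na(stated_total)) sum(occupied) else stated_total
  te_classes <- intersect(cls, c("DNA", "LINE", "SINE", "LTR"))
  te_occ <- sum(occupied[match(te_classes, cls)])
  tab <- data.frame(class = cls, element_count = counts,
                    occupied_bp = occupied,
                    percent_of_genome =
                      round_half_up(100 * occupied / assembly_len, 2),
                    stringsAsFactors = FALSE)
  list(table = tab, total_occupied = total,
       total_percent = round_half_up(100 * total / assembly_len, 2),
       te_fraction_of_repeats =
         if (total > 0) round_half_up(100 * te_occ / total, 2) else 0)
}

#' Summarise functional annotation counts
#'
#' @param counts Named vector of gene counts per annotation source.
#' @param total_genes Total number of predicted genes.
#' @return A data frame with `source`, `gene_count` and `percent_of_genes`
#'   (2 decimals, half-up), with a final `Total` row.
#' @export
annotation_summary <- function(counts, total_genes) {
  if (any(counts > total_genes)) {
    stop("annotation count exceeds the total gene count")
  }
  data.frame(source = c(names(counts), "Total"),
             gene_count = c(as.numeric(counts), total_genes),
             percent_of_genes = round_half_up(
               100 * c(as.numeric(counts), total_genes) / total_genes, 2),
             stringsAsFactors = FALSE)
}

#' Consensus quality value from homozygous variant calls
#'
#' Homozygous variants called from read alignments against the assembly
#' mark consensus errors; their per-base rate converts to a Phred-scaled
#' quality `QV = floor(-10 log10(rate))`, floored because the value is
#' reported as an integer class and capped at `qv_cap`. Zero variant sites
#' report the cap with a flag.
#'
#' @param homozygous_variant_sites Number of homozygous variant sites.
#' @param assembly_len Assembly length in bp.
#' @param qv_cap Upper bound on the reported QV.
#' @return A list with `qv`, `rate` and `capped`.
#' @export
consensus_qv <- function(homozygous_variant_sites, assembly_len,
                         qv_cap = 60L) {
  if (homozygous_variant_sites < 0) stop("variant count must be >= 0")
  if (assembly_len <= 0) stop("assembly length must be positive")
  rate <- homozygous_variant_sites / assembly_len
  if (homozygous_variant_sites == 0) {
    return(list(qv = as.integer(qv_cap), rate = 0, capped = TRUE))
  }
  qv <- floor(-10 * log10(rate))
  list(qv = as.integer(min(qv, qv_cap)), rate = rate, capped = qv > qv_cap)
}

#' Assembly length as a percentage of the estimated genome size
#'
#' @param assembly_len Assembly length in bp.
#' @param estimate A [estimate_genome_size()] result, or the estimated
#'   genome size in bp.
#' @return Percent to one decimal, half-up (no clamping).
#' @export
genome_size_concordance <- function(assembly_len, estimate) {
  G <- if (inherits(estimate, "genome_size_estimate")) estimate$G else
    as.numeric(estimate)
  if (G <= 0) stop("estimated genome size must be positive")
  round_half_up(100 * assembly_len / G, 1)
}
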