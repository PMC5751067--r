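#' Detect perfect microsatellites (SSRs)
#'
#' MISA-style detection of maximal perfect tandem repeats with unit lengths
#' 1-7. Defaults require 10 repeats for mononucleotide motifs, 6 for
#' dinucleotide and 5 for tri- through heptanucleotide motifs. Runs whose
#' motif is itself periodic (ATAT = 2 x AT) are reported at the smallest
#' period; windows containing N terminate runs; only whole repeat units are
#' counted.
#'
#' @param contigs Sequences (any container accepted by the package).
#' @param min_units Named integer vector mapping unit length to the minimum
#'   unit count.
#' @param max_unit_len Longest repeat unit considered.
#' @return A data frame of perfect loci sorted by (contig, start):
#'   `contig_id`, `start`, `end` (0-based half-open), `motif`,
#'   `canonical_motif`, `unit_len`, `n_units`, `kind`.
#' @export
find_ssrs <- function(contigs,
                      min_units = c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L,
                                    `5` = 5L, `6` = 5L, `7` = 5L),
                      max_unit_len = 7L) {
  seqs <- as_sequences(contigs)
  mu <- as.integer(min_units[as.character(seq_len(max_unit_len))])
  if (anyNA(mu)) stop("min_units must cover unit lengths 1..", max_unit_len)
  res <- lapply(names(seqs), function(id) {
    hits <- ssr_scan_cpp(seqs[[id]], mu, as.integer(max_unit_len))
    if (nrow(hits) == 0) return(NULL)
    motif <- substr(rep(seqs[[id]], nrow(hits)), hits$start + 1L,
                    hits$start + hits$unit_len)
    data.frame(contig_id = id, start = hits$start, end = hits$end,
               motif = motif, canonical_motif = canonical_motif(motif),
               unit_len = hits$unit_len, n_units = hits$n_units,
               kind = "perfect", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      canonical_motif = character(), unit_len = integer(),
                      n_units = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical form of a repeat motif
#'
#' The lexicographically smallest string among all rotations of the motif
#' and of its reverse complement, pooling the equivalent ways one
#' microsatellite can be read ((AT)n vs (TA)n, either strand).
#'
#' @param motif Character vector of repeat units.
#' @return Character vector of canonical motifs.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    rot <- function(s) {
      vapply(seq_len(u) - 1L,
             function(r) paste0(substr(s, r + 1L, u), substr(s, 1L, r)), "")
    }
    min(c(rot(m), rot(revcomp(m))))
  }, "", USE.NAMES = FALSE)
}

#' Fuse nearby perfect SSRs into compound loci
#'
#' Consecutive perfect SSRs on one contig separated by at most
#' `max_interruption` bases are fused (transitively) into a compound locus
#' spanning from the first start to the last end; the constituents are
#' recorded and withdrawn from the perfect list.
#'
#' @param perfect Perfect loci from [find_ssrs()] (sorted).
#' @param max_interruption Maximum spacer in bp.
#' @return A list with `compound` (a data frame whose `members` list column
#'   holds the constituent loci) and `perfect` (the surviving perfect loci).
#' @export
find_compound_ssrs <- function(perfect, max_interruption = 100L) {
  p <- perfect[order(perfect$contig_id, perfect$start), , drop = FALSE]
  n <- nrow(p)
  empty_compound <- data.frame(contig_id = character(), start = integer(),
                               end = integer(), motif = character(),
                               canonical_motif = character(),
                               unit_len = integer(), n_units = integer(),
                               kind = character(), stringsAsFactors = FALSE)
  empty_compound$members <- list()
  if (n == 0) return(list(compound = empty_compound, perfect = p))
  grp <- cumsum(c(1L, as.integer(
    p$contig_id[-1] != p$contig_id[-n] |
      p$start[-1] - p$end[-n] > max_interruption)))
  comp_rows <- list()
  in_compound <- rep(FALSE, n)
  for (g in split(seq_len(n), grp)) {
    if (length(g) < 2) next
    in_compound[g] <- TRUE
    members <- p[g, , drop = FALSE]
    comp_rows[[length(comp_rows) + 1L]] <- local({
      row <- data.frame(contig_id = members$contig_id[1],
                        start = min(members$start), end = max(members$end),
                        motif = paste(members$motif, collapse = "+"),
                        canonical_motif = NA_character_,
                        unit_len = NA_integer_, n_units = NA_integer_,
                        kind = "compound", stringsAsFactors = FALSE)
      row$members <- list(members)
      row
    })
  }
  compound <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    empty_compound
  rownames(compound) <- NULL
  surv <- p[!in_compound, , drop = FALSE]
  rownames(surv) <- NULL
  list(compound = compound, perfect = surv)
}

#' Select SSR loci usable as genetic markers
#'
#' Applies the four marker criteria: (i) perfect repeats with unit length
#' 2-4 and at least 6/5/5 units respectively (mono- and penta-plus motifs
#' are not eligible); (ii) no other SSR locus within
#' `marker_flank_exclusion` bp (default 2 kb) of either boundary; (iii) the
#' locus does not intersect the repeat mask; (iv) each
#' `marker_flank_len`-bp (default 200 bp) flank occurs exactly once in the
#' assembly as an exact match, counting both strands - candidates whose
#' flank is truncated by a contig end fail. Criterion (iv) is evaluated
#' only for candidates passing (i)-(iii) (it is the expensive one) and is
#' `NA` otherwise.
#'
#' @param perfect Perfect loci from [find_ssrs()] (after compound fusion).
#' @param contigs The assembly the loci were detected on.
#' @param repeat_mask Optional interval data frame of repeat regions.
#' @param cfg A [pipeline_config()].
#' @param other_loci Additional loci (e.g. compound SSRs) counted as
#'   neighbours for criterion (ii).
#' @return A data frame of marker candidates: the locus columns plus
#'   `flank5`, `flank3`, the four criterion columns
#'   (`crit_perfect_min_units`, `crit_flank_ssr_free`,
#'   `crit_outside_repeat`, `crit_flanks_unique`) and `selected`.
#' @export
select_markers <- function(perfect, contigs, repeat_mask = NULL,
                           cfg = pipeline_config(), other_loci = NULL) {
  seqs <- as_sequences(contigs)
  loci <- perfect
  n <- nrow(loci)
  neighbours <- rbind(
    loci[, c("contig_id", "start", "end")],
    if (!is.null(other_loci) && nrow(other_loci) > 0)
      other_loci[, c("contig_id", "start", "end")])

  min_by_unit <- c(`2` = 6L, `3` = 5L, `4` = 5L)
  crit1 <- loci$kind == "perfect" &
    loci$unit_len %in% 2:4 &
    loci$n_units >= min_by_unit[as.character(loci$unit_len)]
  crit1[is.na(crit1)] <- FALSE

  win <- cfg$marker_flank_exclusion
  crit2 <- vapply(seq_len(n), function(i) {
    same <- neighbours$contig_id == loci$contig_id[i]
    other <- same & !(neighbours$start == loci$start[i] &
                        neighbours$end == loci$end[i])
    !any(other &
           neighbours$end > loci$start[i] - win &
           neighbours$start < loci$end[i] + win)
  }, TRUE)

  crit3 <- rep(TRUE, n)
  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0) {
    crit3 <- vapply(seq_len(n), function(i) {
      m <- repeat_mask[repeat_mask$seq_id == loci$contig_id[i], , drop = FALSE]
      !any(m$end > loci$start[i] & m$start < loci$end[i])
    }, TRUE)
  }

  flen <- cfg$marker_flank_len
  flank5 <- flank3 <- rep(NA_character_, n)
  crit4 <- rep(NA, n)
  cand <- which(crit1 & crit2 & crit3)
  if (length(cand)) {
    subject <- Biostrings::DNAStringSet(clean_dna(unname(seqs)))
    for (i in cand) {
      s <- seqs[[loci$contig_id[i]]]
      if (loci$start[i] < flen || loci$end[i] + flen > nchar(s)) {
        crit4[i] <- FALSE
        next
      }
      f5 <- substr(s, loci$start[i] - flen + 1L, loci$start[i])
      f3 <- substr(s, loci$end[i] + 1L, loci$end[i] + flen)
      flank5[i] <- f5; flank3[i] <- f3
      crit4[i] <- flank_occurrences(f5, subject) == 1L &&
        flank_occurrences(f3, subject) == 1L
    }
  }

  out <- loci
  out$flank5 <- flank5
  out$flank3 <- flank3
  out$crit_perfect_min_units <- crit1
  out$crit_flank_ssr_free <- crit2
  out$crit_outside_repeat <- crit3
  out$crit_flanks_unique <- crit4
  out$selected <- crit1 & crit2 & crit3 & !is.na(crit4) & crit4
  out
}

# exact occurrence count of a flank in the assembly, both strands
flank_occurrences <- function(flank, subject) {
  if (grepl("N", flank, fixed = TRUE)) return(0L)
  pat <- Biostrings::DNAString(flank)
  fwd <- sum(Biostrings::vcountPattern(pat, subject))
  rev <- sum(Biostrings::vcountPattern(
    Biostrings::reverseComplement(pat), subject))
  fwd + rev
}

#' Tabulate SSR motif frequencies
#'
#' Counts loci per canonical motif and reports the most frequent SSR type
#' (raw motif and unit count) among loci with unit length >= 2, ties broken
#' lexicographically.
#'
#' @param loci Perfect loci from [find_ssrs()].
#' @return A list with `motifs` (data frame `canonical_motif`, `count`,
#'   sorted by decreasing count then motif) and `top_type` (one-row data
#'   frame `motif`, `n_units`, `count`, or `NULL` when no such locus).
#' @export
motif_frequency_table <- function(loci) {
  if (nrow(loci) == 0) {
    return(list(motifs = data.frame(canonical_motif = character(),
                                    count = integer(),
                                    stringsAsFactors = FALSE),
                top_type = NULL))
  }
  tab <- table(loci$canonical_motif)
  motifs <- data.frame(canonical_motif = names(tab),
                       count = as.integer(tab), stringsAsFactors = FALSE)
  motifs <- motifs[order(-motifs$count, motifs$canonical_motif), ,
                   drop = FALSE]
  rownames(motifs) <- NULL

  multi <- loci[loci$unit_len >= 2, , drop = FALSE]
  top_type <- NULL
  if (nrow(multi) > 0) {
    key <- paste0("(", multi$motif, ")", multi$n_units)
    tt <- table(key)
    best <- sort(names(tt)[tt == max(tt)])[1]
    row <- multi[match(best, key), ]
    top_type <- data.frame(motif = row$motif, n_units = row$n_units,
                           count = as.integer(max(tt)),
                           stringsAsFactors = FALSE)
  }
  list(motifs = motifs, top_type = top_type)
}
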