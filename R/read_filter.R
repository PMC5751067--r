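#' Clean a single short read
#'
#' Applies the five-rule Illumina cleaning policy in a fixed order:
#' adapter screen, fixed end-trimming, N-fraction filter, and
#' low-quality-fraction filter (PCR-duplicate removal operates on pairs, see
#' [remove_duplicates()]). A read containing any adapter as an exact
#' substring is discarded. Trimming removes `trim5` bases from the 5' end
#' and `trim3` bases from the 3' end unconditionally; both fraction filters
#' are evaluated on the post-trim sequence with strict inequalities.
#'
#' @param read A list with `id`, `sequence` and integer `quality`.
#' @param adapters Character vector of adapter sequences.
#' @param n_fraction_max Discard when the N fraction exceeds this value.
#' @param lowq_phred_max A base is "low quality" when its Phred score is at
#'   or below this value.
#' @param lowq_fraction_max Discard when the low-quality fraction exceeds
#'   this value.
#' @param trim5,trim3 Bases trimmed from each end.
#' @return A list with `kept` (logical), `rule` (`NA` when kept, otherwise
#'   one of `adapter`, `too_short`, `n_fraction`, `low_quality`), `record`
#'   (the trimmed read when kept) and `bases_trimmed`.
#' @export
clean_read <- function(read, adapters = character(),
                       n_fraction_max = 0.10, lowq_phred_max = 5L,
                       lowq_fraction_max = 0.50, trim5 = 2L, trim3 = 3L) {
  stopifnot(!is.null(read$quality))
  seq <- read$sequence
  n <- nchar(seq)
  discard <- function(rule) list(kept = FALSE, rule = rule, record = NULL,
                                 bases_trimmed = 0L)
  for (ad in adapters) {
    if (nzchar(ad) && grepl(ad, seq, fixed = TRUE)) return(discard("adapter"))
  }
  if (n < trim5 + trim3 + 1L) return(discard("too_short"))
  seq2 <- substr(seq, trim5 + 1L, n - trim3)
  qual2 <- read$quality[seq.int(trim5 + 1L, n - trim3)]
  n2 <- nchar(seq2)
  n_frac <- lengths(regmatches(seq2, gregexpr("N", seq2, fixed = TRUE))) / n2
  if (n_frac > n_fraction_max) return(discard("n_fraction"))
  if (sum(qual2 <= lowq_phred_max) / n2 > lowq_fraction_max) {
    return(discard("low_quality"))
  }
  list(kept = TRUE, rule = NA_character_,
       record = list(id = read$id, sequence = seq2, quality = qual2),
       bases_trimmed = as.integer(trim5 + trim3))
}

#' Clean a set of reads and report per-rule discard counts
#'
#' @param reads A record data frame (see [read_sequences()]) with a
#'   `quality` column.
#' @param ... Passed to [clean_read()].
#' @return A list with `reads` (the kept, trimmed records) and `report`, a
#'   [filter_report()] whose counts satisfy
#'   `input_reads == kept_reads + sum(discarded_by_rule)`.
#' @export
clean_reads <- function(reads, ...) {
  rules <- c(adapter = 0L, n_fraction = 0L, duplicate = 0L,
             low_quality = 0L, too_short = 0L)
  kept <- vector("list", nrow(reads))
  trimmed <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- list(id = reads$id[i], sequence = reads$sequence[i],
              quality = reads$quality[[i]])
    res <- clean_read(r, ...)
    if (res$kept) {
      kept[[i]] <- res$record
      trimmed <- trimmed + res$bases_trimmed
    } else {
      rules[res$rule] <- rules[res$rule] + 1L
    }
  }
  kept <- kept[!vapply(kept, is.null, TRUE)]
  out <- data.frame(id = vapply(kept, `[[`, "", "id"),
                    sequence = vapply(kept, `[[`, "", "sequence"),
                    stringsAsFactors = FALSE)
  out$quality <- lapply(kept, `[[`, "quality")
  list(reads = out,
       report = filter_report(nrow(reads), nrow(out), rules, trimmed))
}

#' Assemble a read-filter report
#'
#' @param input_reads,kept_reads Read counts.
#' @param discarded_by_rule Named integer vector of per-rule discards.
#' @param bases_trimmed Total trimmed bases.
#' @return A list of class `filter_report`.
#' @export
filter_report <- function(input_reads, kept_reads, discarded_by_rule,
                          bases_trimmed = 0L) {
  if (input_reads != kept_reads + sum(discarded_by_rule)) {
    stop("filter report does not conserve reads")
  }
  structure(list(input_reads = as.integer(input_reads),
                 kept_reads = as.integer(kept_reads),
                 discarded_by_rule = discarded_by_rule,
                 bases_trimmed = as.integer(bases_trimmed)),
            class = "filter_report")
}

#' Remove PCR duplicates from read pairs
#'
#' A pair is a duplicate when its `(r1, r2)` sequence tuple is byte-identical
#' to an earlier pair's; the first occurrence is kept and input order is
#' preserved. Ids and quality strings are deliberately ignored: PCR
#' duplicates share sequence, not quality.
#'
#' @param pairs A list of pairs, each a list with `r1` and (optionally) `r2`
#'   read records.
#' @return A list with `pairs` (deduplicated) and `report`.
#' @export
remove_duplicates <- function(pairs) {
  keys <- vapply(pairs, function(p) {
    paste(p$r1$sequence, if (is.null(p$r2)) "" else p$r2$sequence, sep = "\r")
  }, "")
  dup <- duplicated(keys)
  report <- filter_report(length(pairs), sum(!dup),
                          c(adapter = 0L, n_fraction = 0L,
                            duplicate = sum(dup), low_quality = 0L,
                            too_short = 0L))
  list(pairs = pairs[!dup], report = report)
}
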