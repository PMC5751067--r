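#' Construct an alignment-block table
#'
#' Alignment blocks are the atoms of the haplotig purge: one local match
#' between two contigs. All coordinates are 0-based half-open on the forward
#' strand of each sequence; minus-strand blocks still satisfy
#' `t_start < t_end`, with `strand == "-"` recording the orientation of the
#' query relative to the target.
#'
#' @param query_id,target_id Character vectors of contig ids.
#' @param q_start,q_end,t_start,t_end Integer coordinates.
#' @param strand `"+"` or `"-"`.
#' @param matched_bases Number of exactly matching bases in the block.
#' @param identity Fraction in `[0, 1]`; for internally generated blocks this
#'   equals `matched_bases / max(q_end - q_start, t_end - t_start)`.
#' @param score Aligner score (matched bases for internal blocks).
#' @param evalue Optional E-value (BLAST-derived blocks).
#' @param source One of `"internal"`, `"paf"`, `"coords"`, `"blast6"`.
#' @param q_len,t_len Optional full sequence lengths (carried by PAF).
#' @return A validated data frame of alignment blocks.
#' @export
alignment_blocks <- function(query_id = character(), target_id = character(),
                             q_start = integer(), q_end = integer(),
                             t_start = integer(), t_end = integer(),
                             strand = character(),
                             matched_bases = integer(),
                             identity = numeric(), score = numeric(),
                             evalue = NA_real_, source = "internal",
                             q_len = NA_integer_, t_len = NA_integer_) {
  n <- length(query_id)
  out <- data.frame(query_id = as.character(query_id),
                    target_id = as.character(target_id),
                    q_start = as.integer(q_start), q_end = as.integer(q_end),
                    t_start = as.integer(t_start), t_end = as.integer(t_end),
                    strand = rep_len(strand, n),
                    matched_bases = as.numeric(matched_bases),
                    identity = as.numeric(identity),
                    score = as.numeric(score),
                    evalue = rep_len(as.numeric(evalue), n),
                    source = rep_len(source, n),
                    q_len = rep_len(as.integer(q_len), n),
                    t_len = rep_len(as.integer(t_len), n),
                    stringsAsFactors = FALSE)
  validate_blocks(out)
  out
}

validate_blocks <- function(b) {
  if (nrow(b) == 0) return(invisible(b))
  if (any(b$q_end <= b$q_start) || any(b$t_end <= b$t_start)) {
    stop("alignment block spans must be non-empty (end > start)")
  }
  span_min <- pmin(b$q_end - b$q_start, b$t_end - b$t_start)
  if (any(b$matched_bases > span_min)) {
    stop("matched_bases exceeds the shorter block span")
  }
  if (!all(b$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(b)
}

#' Parse an alignment table (PAF, MUMmer show-coords, or BLAST outfmt 6)
#'
#' Converts any of the three tabular dialects to the package's internal
#' 0-based half-open forward-strand convention. PAF is already 0-based
#' half-open; `show-coords -T -H` and BLAST outfmt 6 are 1-based inclusive,
#' with minus-strand alignments indicated by reversed coordinates (second
#' sequence for coords, subject for blast6).
#'
#' @param path Path to the table.
#' @param dialect `"paf"`, `"coords"` or `"blast6"`.
#' @param seq_lengths Optional named vector of sequence lengths; when given,
#'   coordinates are validated against it.
#' @return An alignment-block data frame (see [alignment_blocks()]).
#' @export
parse_alignment_table <- function(path, dialect = c("paf", "coords", "blast6"),
                                  seq_lengths = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- c(paf = 12L, coords = 9L, blast6 = 12L)[dialect]
  nf <- lengths(fields)
  bad <- which(if (dialect == "paf") nf < need else nf != need)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected %s%d tab-separated columns, found %d",
                 dialect, bad[1], if (dialect == "paf") ">= " else "",
                 need, nf[bad[1]]))
  }
  if (length(fields) == 0) return(alignment_blocks())
  m <- do.call(rbind, lapply(fields, `[`, seq_len(need)))

  blocks <- switch(dialect,
    paf = {
      qs <- as.integer(m[, 3]); qe <- as.integer(m[, 4])
      ts <- as.integer(m[, 8]); te <- as.integer(m[, 9])
      nmatch <- as.numeric(m[, 10]); alen <- as.numeric(m[, 11])
      alignment_blocks(query_id = m[, 1], target_id = m[, 6],
                       q_start = qs, q_end = qe, t_start = ts, t_end = te,
                       strand = m[, 5],
                       matched_bases = pmin(nmatch, pmin(qe - qs, te - ts)),
                       identity = nmatch / pmax(alen, 1),
                       score = nmatch, source = "paf",
                       q_len = as.integer(m[, 2]), t_len = as.integer(m[, 7]))
    },
    coords = {
      # show-coords -T -H: S1 E1 S2 E2 LEN1 LEN2 %IDY ref qry
      s1 <- as.integer(m[, 1]); e1 <- as.integer(m[, 2])
      s2 <- as.integer(m[, 3]); e2 <- as.integer(m[, 4])
      idy <- as.numeric(m[, 7]) / 100
      minus <- s2 > e2
      qs <- ifelse(minus, e2 - 1L, s2 - 1L)
      qe <- ifelse(minus, s2, e2)
      ts <- s1 - 1L; te <- e1
      span_min <- pmin(qe - qs, te - ts)
      alignment_blocks(query_id = m[, 9], target_id = m[, 8],
                       q_start = qs, q_end = qe, t_start = ts, t_end = te,
                       strand = ifelse(minus, "-", "+"),
                       matched_bases = round(idy * span_min),
                       identity = idy, score = round(idy * span_min),
                       source = "coords")
    },
    blast6 = {
      # qseqid sseqid pident length mismatch gapopen qstart qend sstart send
      # evalue bitscore
      qs <- as.integer(m[, 7]) - 1L; qe <- as.integer(m[, 8])
      ss <- as.integer(m[, 9]); se <- as.integer(m[, 10])
      idy <- as.numeric(m[, 3]) / 100
      minus <- ss > se
      ts <- ifelse(minus, se - 1L, ss - 1L)
      te <- ifelse(minus, ss, se)
      span_min <- pmin(qe - qs, te - ts)
      alignment_blocks(query_id = m[, 1], target_id = m[, 2],
                       q_start = qs, q_end = qe, t_start = ts, t_end = te,
                       strand = ifelse(minus, "-", "+"),
                       matched_bases = round(idy * span_min),
                       identity = idy, score = as.numeric(m[, 12]),
                       evalue = as.numeric(m[, 11]), source = "blast6")
    })

  if (!is.null(seq_lengths)) {
    check_block_bounds(blocks, seq_lengths)
  }
  blocks
}

check_block_bounds <- function(blocks, seq_lengths) {
  for (side in c("query", "target")) {
    ids <- if (side == "query") blocks$query_id else blocks$target_id
    ends <- if (side == "query") blocks$q_end else blocks$t_end
    known <- ids %in% names(seq_lengths)
    over <- known & ends > seq_lengths[ids]
    if (any(over)) {
      stop(sprintf("block %d: %s coordinates exceed length of %s",
                   which(over)[1], side, ids[which(over)[1]]))
    }
  }
  invisible(blocks)
}

#' Write an alignment-block table in one of the supported dialects
#'
#' The inverse of [parse_alignment_table()]: parse-write-parse round-trips
#' are identity on the fields each dialect carries.
#'
#' @param blocks An alignment-block data frame.
#' @param path Output path.
#' @param dialect `"paf"`, `"coords"` or `"blast6"`.
#' @param seq_lengths Named lengths used to fill PAF length columns when the
#'   blocks do not carry them.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(blocks, path,
                                  dialect = c("paf", "coords", "blast6"),
                                  seq_lengths = NULL) {
  dialect <- match.arg(dialect)
  b <- blocks
  len_of <- function(ids, have) {
    out <- have
    if (!is.null(seq_lengths)) {
      miss <- is.na(out) & ids %in% names(seq_lengths)
      out[miss] <- seq_lengths[ids[miss]]
    }
    out[is.na(out)] <- 0L
    out
  }
  lines <- switch(dialect,
    paf = {
      qlen <- len_of(b$query_id, b$q_len)
      tlen <- len_of(b$target_id, b$t_len)
      sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
              b$query_id, qlen, b$q_start, b$q_end, b$strand,
              b$target_id, tlen, b$t_start, b$t_end,
              as.integer(round(b$matched_bases)),
              pmax(b$q_end - b$q_start, b$t_end - b$t_start), 255L)
    },
    coords = {
      minus <- b$strand == "-"
      s2 <- ifelse(minus, b$q_end, b$q_start + 1L)
      e2 <- ifelse(minus, b$q_start + 1L, b$q_end)
      sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
              b$t_start + 1L, b$t_end, s2, e2,
              b$t_end - b$t_start, b$q_end - b$q_start,
              b$identity * 100, b$target_id, b$query_id)
    },
    blast6 = {
      minus <- b$strand == "-"
      ss <- ifelse(minus, b$t_end, b$t_start + 1L)
      se <- ifelse(minus, b$t_start + 1L, b$t_end)
      alen <- pmax(b$q_end - b$q_start, b$t_end - b$t_start)
      mism <- pmax(0L, as.integer(round((1 - b$identity) * alen)))
      ev <- ifelse(is.na(b$evalue), 0, b$evalue)
      sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2g\t%.1f",
              b$query_id, b$target_id, b$identity * 100, alen, mism, 0L,
              b$q_start + 1L, b$q_end, ss, se, ev, b$score)
    })
  writeLines(lines, path)
  invisible(path)
}
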