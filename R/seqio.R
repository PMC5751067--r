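#' Read sequences from FASTA or FASTQ
#'
#' Reads a sequence file into a data frame of records. Sequences are
#' uppercased on read and any IUPAC ambiguity letter other than A/C/G/T is
#' replaced by `N`. Record ids (the first whitespace-delimited token of each
#' header) must be unique within a file.
#'
#' @param path Path to the sequence file.
#' @param format Either `"fasta"` or `"fastq"`. FASTQ qualities are decoded
#'   from Phred+33.
#' @param mask_lowercase If `TRUE`, runs of lowercase (soft-masked) bases are
#'   returned as an interval data frame in the `"softmask"` attribute of the
#'   result, so masked FASTAs can double as repeat-mask carriers.
#' @return A data frame with columns `id`, `sequence` and (for FASTQ) a
#'   `quality` list column of integer Phred scores.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"),
                           mask_lowercase = FALSE) {
  format <- match.arg(format)
  x <- Biostrings::readBStringSet(path, format = format,
                                  with.qualities = (format == "fastq"))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  raw_seq <- as.character(x)
  names(raw_seq) <- NULL
  if (mask_lowercase) {
    mask <- lowercase_runs(raw_seq, ids)
  }
  seqs <- clean_dna(raw_seq)
  out <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
  if (format == "fastq") {
    quals <- as.character(S4Vectors::mcols(x)$qualities)
    out$quality <- lapply(quals, decode_phred)
    bad <- which(nchar(quals) != nchar(seqs))
    if (length(bad)) {
      stop("quality length mismatch for record ", ids[bad[1]])
    }
  }
  if (mask_lowercase) attr(out, "softmask") <- mask
  out
}

# uppercase and collapse non-ACGT letters to N
clean_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

lowercase_runs <- function(seqs, ids) {
  res <- lapply(seq_along(seqs), function(i) {
    m <- gregexpr("[a-z]+", seqs[[i]])[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(seq_id = ids[i], start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out
}

decode_phred <- function(q) utf8ToInt(q) - 33L

encode_phred <- function(q) intToUtf8(q + 33L)

#' Write sequences to FASTA or FASTQ
#'
#' @param records A record data frame as returned by [read_sequences()], or a
#'   named character vector of sequences (FASTA only).
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires a `quality` column.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  if (format == "fastq") {
    if (is.null(records$quality)) stop("FASTQ output needs a quality column")
    q <- if (is.character(records$quality)) {
      Biostrings::BStringSet(records$quality)
    } else {
      Biostrings::BStringSet(vapply(records$quality, encode_phred, ""))
    }
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

# Normalise the various sequence containers accepted across the package
# (record data frame, named character vector, XStringSet) to a named
# character vector of uppercase sequences.
as_sequences <- function(x) {
  if (is.data.frame(x)) {
    out <- setNames(x$sequence, x$id)
  } else if (methods::is(x, "XStringSet")) {
    out <- setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    if (length(x) > 0 && is.null(names(x))) stop("sequences must be named")
    out <- x
  } else {
    stop("cannot interpret object of class ", class(x)[1], " as sequences")
  }
  if (anyDuplicated(names(out))) stop("duplicate sequence ids")
  out
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
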