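#' Count k-mers into a multiplicity histogram
#'
#' Builds the k-mer spectrum of a sequence set: for each multiplicity `m`,
#' the number of distinct k-mers seen exactly `m` times. Windows containing
#' `N` (or any non-ACGT letter) are skipped. With `canonical = TRUE`
#' (Jellyfish-style, the form depth peaks are defined on) each k-mer is
#' pooled with its reverse complement under the lexicographically smaller
#' representative.
#'
#' @param seqs Sequences: a record data frame, named character vector, or
#'   `XStringSet`. Unnamed character vectors are accepted for reads.
#' @param k k-mer length (1-31).
#' @param canonical Pool reverse complements?
#' @return An object of class `kmer_histogram`: a list with `k`, `counts`
#'   (data frame of `multiplicity`, `distinct`) and `canonical`.
#' @export
count_kmers <- function(seqs, k, canonical = TRUE) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  h <- kmer_histogram_cpp(as.character(seqs), as.integer(k), canonical)
  kmer_histogram(k, h, canonical)
}

#' @rdname count_kmers
#' @param counts A data frame with columns `multiplicity` and `distinct`, or
#'   a named numeric vector (names are multiplicities).
#' @export
kmer_histogram <- function(k, counts, canonical = TRUE) {
  if (!is.data.frame(counts)) {
    counts <- data.frame(multiplicity = as.integer(names(counts)),
                         distinct = as.numeric(counts))
  }
  counts <- counts[order(counts$multiplicity), , drop = FALSE]
  rownames(counts) <- NULL
  if (any(counts$multiplicity < 1)) stop("multiplicities must be >= 1")
  if (any(counts$distinct < 0)) stop("counts must be >= 0")
  structure(list(k = as.integer(k), counts = counts,
                 canonical = isTRUE(canonical)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k = %d, %s)\n", x$k,
              if (x$canonical) "canonical" else "stranded"))
  cat(sprintf("  distinct k-mers: %s\n",
              format(sum(x$counts$distinct), big.mark = ",")))
  cat(sprintf("  total k-mers:    %s\n",
              format(kmer_total(x), big.mark = ",")))
  invisible(x)
}

#' Total k-mer count of a histogram
#'
#' `K_total = sum over m of m * counts[m]`.
#'
#' @param hist A `kmer_histogram`.
#' @param multiplicity_max If finite, sum only multiplicities up to this
#'   value (used for the error k-mer count `K_error`).
#' @return A numeric count.
#' @export
kmer_total <- function(hist, multiplicity_max = Inf) {
  keep <- hist$counts$multiplicity <= multiplicity_max
  sum(hist$counts$multiplicity[keep] * hist$counts$distinct[keep])
}

#' Locate the coverage peak depth of a k-mer spectrum
#'
#' The homozygous-coverage peak is the multiplicity maximising the distinct
#' k-mer count beyond the error valley, where the valley is the first local
#' minimum of the histogram at multiplicity `>= min_valley_search`. Ties
#' break toward smaller multiplicity. A spectrum that decreases
#' monotonically over its whole support has no coverage peak and raises an
#' error.
#'
#' @param hist A `kmer_histogram`.
#' @param min_valley_search Smallest multiplicity considered for the valley.
#' @return Integer peak depth `D`.
#' @export
find_peak_depth <- function(hist, min_valley_search = 2L) {
  counts <- hist$counts
  if (nrow(counts) == 0) stop("empty k-mer histogram")
  if (nrow(counts) == 1) return(counts$multiplicity[1])
  m <- counts$multiplicity
  d <- counts$distinct
  n <- length(m)
  valley <- NA_integer_
  for (i in seq_len(n)) {
    if (m[i] < min_valley_search) next
    left_ok <- i == 1 || d[i - 1] >= d[i]
    right_ok <- i < n && d[i + 1] > d[i]
    if (left_ok && right_ok) { valley <- m[i]; break }
  }
  if (is.na(valley)) {
    if (all(diff(d) <= 0)) {
      stop("no coverage peak: histogram decreases over its whole support")
    }
    cand <- which(m >= min_valley_search)
    if (length(cand) == 0) stop("no coverage peak beyond the error region")
    return(m[cand[which.max(d[cand])]])
  }
  cand <- which(m > valley)
  if (length(cand) == 0) stop("no coverage peak beyond the error valley")
  m[cand[which.max(d[cand])]]
}

#' Estimate genome size from a k-mer spectrum
#'
#' Implements the classical spectrum estimator `G = (K_total - K_error) / D`:
#' the total k-mer count, minus k-mers at error-like low multiplicities, over
#' the coverage peak depth. `K_error` sums multiplicities up to
#' `error_multiplicity_max` (default 1, i.e. k-mers seen once).
#'
#' @param hist A `kmer_histogram`.
#' @param D Peak depth; found with [find_peak_depth()] when `NULL`.
#' @param error_multiplicity_max Largest multiplicity treated as sequencing
#'   error.
#' @return An object of class `genome_size_estimate` with fields `G`,
#'   `K_total`, `K_error`, `D`, `error_multiplicity_max`.
#' @export
estimate_genome_size <- function(hist, D = NULL, error_multiplicity_max = 1L) {
  if (is.null(D)) D <- find_peak_depth(hist)
  genome_size_from_counts(kmer_total(hist),
                          kmer_total(hist, error_multiplicity_max),
                          D, error_multiplicity_max)
}

#' @rdname estimate_genome_size
#' @param K_total,K_error Total and error k-mer counts.
#' @export
genome_size_from_counts <- function(K_total, K_error, D,
                                    error_multiplicity_max = 1L) {
  if (D < 1) stop("peak depth D must be >= 1")
  if (K_error > K_total) stop("K_error cannot exceed K_total")
  G <- round_half_up((K_total - K_error) / D, 0)
  structure(list(G = G, K_total = K_total, K_error = K_error,
                 D = as.integer(D),
                 error_multiplicity_max = as.integer(error_multiplicity_max)),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("Genome size estimate: %s bp (~%s Mb)\n",
              format(x$G, big.mark = ",", scientific = FALSE),
              format(round_half_up(x$G / 1e6, 0))))
  cat(sprintf("  K_total = %s, K_error = %s (m <= %d), D = %d\n",
              format(x$K_total, big.mark = ",", scientific = FALSE),
              format(x$K_error, big.mark = ",", scientific = FALSE),
              x$error_multiplicity_max, x$D))
  invisible(x)
}

# round-half-up at `digits` decimals (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
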