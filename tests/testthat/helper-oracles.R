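# Independent oracles and fixture builders shared across the suite.

# Exhaustive maximum chain weight: enumerate every subset of blocks that is
# strictly increasing in both coordinates by depth-first search (no DP, no
# memoisation) and return the best total weight.
lis_oracle <- function(b) {
  ord <- order(b$q_start, b$t_start)
  b <- b[ord, , drop = FALSE]
  n <- nrow(b)
  minus <- b$strand[1] == "-"
  compat <- function(i, j) {
    b$q_start[j] >= b$q_end[i] &&
      (if (minus) b$t_end[j] <= b$t_start[i] else b$t_start[j] >= b$t_end[i])
  }
  best <- 0
  rec <- function(last, from, w) {
    if (w > best) best <<- w
    if (from > n) return(invisible())
    for (j in from:n) {
      if (last == 0L || compat(last, j)) rec(j, j + 1L, w + b$matched_bases[j])
    }
  }
  rec(0L, 1L, 0)
  best
}

# random one-pair block instance for the chaining oracle
random_block_instance <- function(n, minus = FALSE) {
  q_start <- sort(sample(0:2000, n))
  q_len <- sample(10:120, n, replace = TRUE)
  t_start <- sample(0:2000, n, replace = TRUE)
  t_len <- sample(10:120, n, replace = TRUE)
  w <- sample(5:120, n, replace = TRUE)
  alignment_blocks(query_id = "q", target_id = "t",
                   q_start = q_start, q_end = q_start + q_len,
                   t_start = t_start, t_end = t_start + t_len,
                   strand = if (minus) "-" else "+",
                   matched_bases = pmin(w, pmin(q_len, t_len)),
                   identity = 1, score = w)
}

# Regular-expression SSR oracle: for every unit length, leftmost
# non-overlapping greedy matches of ([ACGT]{u})\1{min-1,}, keeping only
# motifs with no shorter dividing period.
ssr_regex_oracle <- function(seq, min_units = c(10L, 6L, 5L, 5L, 5L, 5L, 5L)) {
  rows <- list()
  for (u in seq_along(min_units)) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, min_units[u] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (i in seq_along(m)) {
      st <- as.integer(m[i])
      len <- attr(m, "match.length")[i]
      motif <- substr(seq, st, st + u - 1L)
      reducible <- FALSE
      for (d in seq_len(u - 1L)) {
        if (u %% d == 0 && strrep(substr(motif, 1, d), u / d) == motif) {
          reducible <- TRUE
          break
        }
      }
      if (reducible) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = st - 1L, end = st - 1L + len, unit_len = u,
        n_units = len %/% u, motif = motif, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      unit_len = integer(), n_units = integer(),
                      motif = character(), stringsAsFactors = FALSE)
  }
  out[order(out$start, out$unit_len), , drop = FALSE]
}

# brute-force longest common substring length (row-vectorised DP)
longest_common_substring <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- integer(length(B))
  best <- 0L
  for (i in seq_along(A)) {
    shifted <- c(0L, prev[-length(prev)])
    cur <- ifelse(B == A[i], shifted + 1L, 0L)
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# quick builders
make_read <- function(seq, qual = rep(40L, nchar(seq)), id = "r1") {
  list(id = id, sequence = seq, quality = qual)
}

one_pair_chain <- function(short_id, long_id, q_start, q_end, t_start, t_end,
                           matched, identity = 1) {
  b <- alignment_blocks(query_id = short_id, target_id = long_id,
                        q_start = q_start, q_end = q_end,
                        t_start = t_start, t_end = t_end, strand = "+",
                        matched_bases = matched, identity = identity,
                        score = matched)
  ch <- chain_lis(b, min_chain_weight = 1)
  lapply(ch, merge_adjacent_blocks)
}
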