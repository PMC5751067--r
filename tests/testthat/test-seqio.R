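test_that("FASTA reading uppercases, keeps file order and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt", ">c2", "NNAA"), f)
  rec <- read_sequences(f, "fasta")
  expect_equal(rec$id, c("c1", "c2"))
  expect_equal(rec$sequence, c("ACGT", "NNAA"))

  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), f)
  expect_error(read_sequences(f, "fasta"), "duplicate")
})

test_that("FASTQ qualities decode from Phred+33", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  rec <- read_sequences(f, "fastq")
  expect_equal(rec$quality[[1]], c(40L, 40L, 40L, 40L))
})

test_that("sequence write/read round-trips for FASTA and FASTQ", {
  rec <- data.frame(id = c("a", "b"),
                    sequence = c("ACGTACGT", "TTTTGGGG"),
                    stringsAsFactors = FALSE)
  rec$quality <- list(c(40L, 40L, 2L, 2L, 30L, 30L, 30L, 30L),
                      rep(17L, 8))
  fq <- withr::local_tempfile(fileext = ".fq")
  write_sequences(rec, fq, "fastq")
  back <- read_sequences(fq, "fastq")
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$quality, rec$quality)

  fa <- withr::local_tempfile(fileext = ".fa")
  write_sequences(rec[, c("id", "sequence")], fa, "fasta")
  expect_equal(read_sequences(fa, "fasta")$sequence, rec$sequence)
})

test_that("soft-masked runs can be exported as intervals", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGTacgtACGT"), f)
  rec <- read_sequences(f, "fasta", mask_lowercase = TRUE)
  expect_equal(rec$sequence, "ACGTACGTACGT")
  mask <- attr(rec, "softmask")
  expect_equal(mask$start, 4L)
  expect_equal(mask$end, 8L)
})

test_that("interval union length collapses overlap and honours half-open ends", {
  expect_equal(interval_union_length(intervals("c", c(0, 300), c(400, 600))),
               600L)
  expect_equal(interval_union_length(intervals("c", c(0, 10), c(10, 20))),
               20L)
  expect_equal(interval_union_length(intervals(character(), integer(),
                                               integer())), 0L)
  expect_error(interval_union_length(intervals(c("a", "b"), c(0, 0),
                                               c(5, 5))), "seq_id")
})

test_that("interval union is permutation/duplication invariant and bounded", {
  withr::local_seed(42)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    st <- sample(0:500, n, replace = TRUE)
    iv <- intervals(rep("c", n), st, st + sample(1:100, n, replace = TRUE))
    u <- interval_union_length(iv)
    perm <- iv[sample(n), , drop = FALSE]
    expect_equal(interval_union_length(perm), u)
    expect_equal(interval_union_length(rbind(iv, iv)), u)
    expect_lte(u, sum(iv$end - iv$start))
  }
  # pairwise disjoint: union equals the sum
  iv <- intervals(rep("c", 3), c(0, 100, 300), c(50, 200, 450))
  expect_equal(interval_union_length(iv), sum(iv$end - iv$start))
})

test_that("alignment dialects convert to 0-based half-open forward coords", {
  td <- withr::local_tempdir()
  paf <- file.path(td, "x.paf")
  writeLines("q\t1000\t100\t200\t-\tt\t2000\t300\t400\t90\t100\t60", paf)
  b <- parse_alignment_table(paf, "paf")
  expect_equal(b$strand, "-")
  expect_lt(b$t_start, b$t_end)
  expect_equal(b$evalue, NA_real_)

  co <- file.path(td, "x.coords")
  writeLines("1\t100\t1\t100\t100\t100\t94.00\tT1\tQ1", co)
  b <- parse_alignment_table(co, "coords")
  expect_equal(b$q_start, 0L)
  expect_equal(b$q_end, 100L)
  expect_equal(b$identity, 0.94)

  b6 <- file.path(td, "x.b6")
  writeLines("q\ts\t95.00\t100\t5\t0\t1\t100\t200\t101\t1e-10\t180.0", b6)
  b <- parse_alignment_table(b6, "blast6")
  expect_equal(b$evalue, 1e-10)
  expect_equal(b$strand, "-")
  expect_equal(c(b$t_start, b$t_end), c(100L, 200L))
})

test_that("alignment parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t100\t1\t100\t100\t100\t94.00\tT1\tQ1", "too\tfew"), f)
  expect_error(parse_alignment_table(f, "coords"), "line 2")
})

test_that("alignment tables round-trip through every dialect", {
  b <- alignment_blocks(query_id = c("q1", "q2"), target_id = c("t1", "t1"),
                        q_start = c(10L, 0L), q_end = c(110L, 250L),
                        t_start = c(5L, 500L), t_end = c(105L, 750L),
                        strand = c("+", "-"),
                        matched_bases = c(95L, 230L),
                        identity = c(0.95, 0.92),
                        score = c(95, 230), evalue = c(1e-20, 1e-8),
                        source = "blast6")
  td <- withr::local_tempdir()
  for (d in c("coords", "blast6")) {
    f <- file.path(td, paste0("rt.", d))
    write_alignment_table(b, f, d)
    back <- parse_alignment_table(f, d)
    expect_equal(back[, c("query_id", "target_id", "q_start", "q_end",
                          "t_start", "t_end", "strand")],
                 b[, c("query_id", "target_id", "q_start", "q_end",
                       "t_start", "t_end", "strand")],
                 info = d)
    expect_equal(back$identity, b$identity, tolerance = 1e-6, info = d)
  }
  b$q_len <- c(300L, 400L)
  b$t_len <- c(800L, 800L)
  f <- file.path(td, "rt.paf")
  write_alignment_table(b, f, "paf")
  back <- parse_alignment_table(f, "paf")
  expect_equal(back[, c("query_id", "q_start", "q_end", "t_start", "t_end",
                        "strand", "q_len", "t_len")],
               b[, c("query_id", "q_start", "q_end", "t_start", "t_end",
                     "strand", "q_len", "t_len")])
})

test_that("coordinates beyond known sequence lengths are rejected", {
  f <- withr::local_tempfile(fileext = ".paf")
  writeLines("q\t1000\t100\t200\t+\tt\t2000\t300\t400\t90\t100\t60", f)
  expect_error(parse_alignment_table(f, "paf", seq_lengths = c(q = 150)),
               "exceed")
})

test_that("config files round-trip and enforce threshold domains", {
  cfg <- pipeline_config(coverage_removal_threshold = 0.75, anchor_k = 19)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  expect_error(pipeline_config(coverage_removal_threshold = 1.2), "0, 1")
  expect_error(pipeline_config(anchor_k = 5), "anchor_k")
})
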