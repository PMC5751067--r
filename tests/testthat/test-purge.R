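test_that("pair coverage unions chain spans on the shorter contig", {
  chains <- one_pair_chain("s", "l", q_start = c(0, 300),
                           q_end = c(400, 600), t_start = c(0, 2300),
                           t_end = c(400, 2600), matched = c(400, 300))
  s <- pair_coverage(chains, c(s = 1000, l = 5000))
  expect_equal(s$short_id, "s")
  expect_equal(s$covered_bp, 600)
  expect_equal(s$coverage_fraction, 0.60)

  empty <- pair_coverage(list(), c(s = 1000, l = 5000))
  expect_equal(empty$coverage_fraction, 0)
})

test_that("the worked haplotig decision removes the short contig", {
  # coverage 83.49% of an 865,792 bp contig against a 2,140,267 bp contig
  # at identity 0.94: above the 80% rule and the 0.90 identity floor
  short_len <- 865792
  long_len <- 2140267
  covered <- round(0.8349 * short_len)
  chains <- one_pair_chain("X000170F", "X000148F", q_start = 0,
                           q_end = covered, t_start = 0, t_end = covered,
                           matched = round(0.94 * covered), identity = 0.94)
  s <- pair_coverage(chains, c(X000170F = short_len, X000148F = long_len))
  expect_equal(round(100 * s$coverage_fraction, 2), 83.49)
  expect_equal(round(s$identity, 2), 0.94)

  contigs <- c(X000170F = "ACGT", X000148F = "ACGTACGT")  # lengths unused
  res <- purge_assembly(contigs, s)
  expect_equal(res$decisions$removed_id, "X000170F")
  expect_false(res$decisions$restored)
  expect_false("X000170F" %in% names(res$kept))
  expect_true("X000148F" %in% names(res$kept))
})

test_that("a removed contig cannot cause further removals", {
  # A covers 85% of B, B covers 85% of C, A longest: B goes, C stays
  summaries <- data.frame(
    short_id = c("B", "C"), long_id = c("A", "B"),
    short_len = c(800, 600), long_len = c(1000, 800),
    covered_bp = c(680, 510), coverage_fraction = c(0.85, 0.85),
    identity = c(0.95, 0.95), stringsAsFactors = FALSE)
  contigs <- setNames(strrep("A", c(1000, 800, 600)), c("A", "B", "C"))
  res <- purge_assembly(contigs, summaries)
  expect_equal(res$decisions$removed_id, "B")
  expect_setequal(names(res$kept), c("A", "C"))
})

test_that("low-identity removals are restored and flagged", {
  summaries <- data.frame(
    short_id = "s", long_id = "l", short_len = 500, long_len = 900,
    covered_bp = 425, coverage_fraction = 0.85, identity = 0.70,
    stringsAsFactors = FALSE)
  res <- purge_assembly(c(s = "ACGT", l = "ACGTACGT"), summaries)
  expect_true(res$decisions$restored)
  expect_equal(res$decisions$reason, "restored_low_identity")
  expect_true("s" %in% names(res$kept))
})

test_that("the operator restore list re-adds contigs and warns on unknowns", {
  summaries <- data.frame(
    short_id = "s", long_id = "l", short_len = 500, long_len = 900,
    covered_bp = 450, coverage_fraction = 0.90, identity = 0.97,
    stringsAsFactors = FALSE)
  contigs <- c(s = "ACGT", l = "ACGTACGT")
  res <- purge_assembly(contigs, summaries, restore_ids = "s")
  expect_true("s" %in% names(res$kept))
  expect_equal(res$decisions$reason, "restored_by_operator")
  expect_warning(purge_assembly(contigs, summaries, restore_ids = "nope"),
                 "never removed")
})

test_that("purging conserves sequence and never removes both pair members", {
  withr::local_seed(6)
  sim <- simulate_diploid_assembly(
    simulation_params(genome_len = 6e5, n_haplotig_pairs = 8,
                      n_unique_contigs = 6, contig_len_range = c(8000, 15000),
                      n_contaminants = 0, seed = 17))
  res <- purge_pipeline(sim$contigs)
  removed <- res$decisions$removed_id[!res$decisions$restored]
  expect_length(intersect(removed, res$decisions$kept_id), 0)
  expect_equal(sum(nchar(res$kept)) + sum(nchar(sim$contigs[removed])),
               sum(nchar(sim$contigs)))

  # idempotence: a second pass on the kept contigs removes nothing
  res2 <- purge_pipeline(res$kept)
  expect_equal(sum(!res2$decisions$restored), 0)
})

test_that("removal decisions export a dot plot for review", {
  withr::local_seed(15)
  seg <- random_dna(3000)
  long_seq <- paste0(random_dna(1000), seg, random_dna(1000))
  short_seq <- seg
  td <- withr::local_tempdir()
  res <- purge_pipeline(c(lg = long_seq, sh = short_seq), dotplot_dir = td)
  expect_equal(res$decisions$removed_id, "sh")
  plots <- list.files(td, pattern = "\\.tsv$")
  expect_length(plots, 1)
  dp <- read.table(file.path(td, plots), header = TRUE, sep = "\t")
  expect_true(all(c("q_start", "t_start") %in% names(dp)))
})

test_that("mitochondrial contigs are flagged by the 80%/1e-5 rule", {
  mk_hits <- function(end, ev) {
    alignment_blocks(query_id = "c1", target_id = "mt", q_start = 0,
                     q_end = end, t_start = 0, t_end = end, strand = "+",
                     matched_bases = end, identity = 1, score = end,
                     evalue = ev, source = "blast6")
  }
  lens <- c(c1 = 1000)
  expect_equal(filter_mitochondrial(mk_hits(850, 1e-10), lens), "c1")
  expect_length(filter_mitochondrial(mk_hits(700, 1e-10), lens), 0)
  expect_length(filter_mitochondrial(mk_hits(850, 1e-3), lens), 0)
  bad <- mk_hits(850, 1e-10)
  bad$evalue <- NA
  expect_error(filter_mitochondrial(bad, lens), "E-value")
})

test_that("blob screening combines coverage and taxon-evidence rules", {
  ann <- data.frame(
    contig_id = c("low", "foreign", "rescued", "clean", "nohit"),
    read_coverage = c(5, 50, 50, 40, 45),
    best_hit_taxon = c("Arthropoda", "Bacteria", "Bacteria", "Arthropoda",
                       NA),
    has_transcript_evidence = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    has_busco_gene = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  v <- filter_contaminants(ann)
  expect_equal(v$keep, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(v$rule[1:2], c("low_coverage", "foreign_no_evidence"))
})
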