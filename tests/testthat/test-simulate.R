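small_params <- function(...) {
  simulation_params(genome_len = 4e5, n_haplotig_pairs = 4,
                    n_unique_contigs = 4, contig_len_range = c(8000, 14000),
                    n_contaminants = 3, ...)
}

test_that("the same seed reproduces the simulation byte for byte", {
  a <- simulate_diploid_assembly(small_params(seed = 10))
  b <- simulate_diploid_assembly(small_params(seed = 10))
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  c <- simulate_diploid_assembly(small_params(seed = 11))
  expect_false(identical(a$contigs, c$contigs))
})

test_that("zero heterozygosity yields identical haplotig pairs", {
  sim <- simulate_diploid_assembly(small_params(heterozygosity = 0,
                                                seed = 12))
  expect_true(all(sim$truth$haplotig_pairs$true_identity == 1))
  # the short contig is literally a substring of its long partner's window
  p <- sim$truth$haplotig_pairs[1, ]
  long_seq <- sim$contigs[[p$kept_expected_id]]
  short_seq <- sim$contigs[[p$removable_id]]
  if (p$true_overlap_fraction == 1) {
    expect_true(grepl(short_seq, long_seq, fixed = TRUE))
  }
})

test_that("contaminants are labelled with their coverage and taxon", {
  sim <- simulate_diploid_assembly(small_params(seed = 13))
  expect_length(sim$truth$contaminant_ids, 3)
  ann <- sim$annotations
  contam <- ann[ann$contig_id %in% sim$truth$contaminant_ids, ]
  expect_true(all(contam$read_coverage == 5))
  expect_true(all(contam$best_hit_taxon != "Arthropoda"))
  # GC shift is visible
  host <- ann[grepl("^ctgU", ann$contig_id), ]
  expect_gt(min(contam$gc), max(host$gc))
})

test_that("blob screening recovers exactly the labelled contaminants", {
  sim <- simulate_diploid_assembly(small_params(seed = 14))
  v <- filter_contaminants(sim$annotations)
  expect_setequal(v$contig_id[!v$keep], sim$truth$contaminant_ids)
})

test_that("the mitochondrial contig is a rotation of its reference", {
  sim <- simulate_diploid_assembly(small_params(seed = 15))
  mt <- sim$contigs[[sim$truth$mito_id]]
  ref <- sim$mito_ref[[1]]
  expect_equal(nchar(mt), nchar(ref))
  expect_true(grepl(mt, strrep(ref, 2), fixed = TRUE))
})

test_that("read simulation hits the expected yield and is seed-stable", {
  withr::local_seed(1)
  contigs <- c(g = random_dna(2e4))
  reads <- simulate_reads(contigs, coverage = 10, read_len = 100, seed = 5)
  expect_equal(nrow(reads), 2000)
  yield <- sum(nchar(reads$sequence))
  expect_lt(abs(yield - 10 * 2e4) / (10 * 2e4), 0.01)
  again <- simulate_reads(contigs, coverage = 10, read_len = 100, seed = 5)
  expect_identical(reads, again)
  expect_error(simulate_reads(contigs, 10, read_len = 3e4), "read_len")
})

test_that("read errors carry low quality scores", {
  withr::local_seed(2)
  contigs <- c(g = random_dna(5000))
  reads <- simulate_reads(contigs, coverage = 5, read_len = 100,
                          error_rate = 0.05, seed = 6)
  qcodes <- unique(strsplit(paste(reads$quality, collapse = ""), "")[[1]])
  expect_setequal(qcodes, c("I", "+"))
  err_frac <- mean(strsplit(paste(reads$quality, collapse = ""),
                            "")[[1]] == "+")
  expect_lt(abs(err_frac - 0.05), 0.02)
})

test_that("purge evaluation scores decisions against the truth", {
  truth <- list(haplotig_pairs = data.frame(
    kept_expected_id = c("L1", "L2"), removable_id = c("S1", "S2"),
    stringsAsFactors = FALSE))
  dec <- function(ids, restored = FALSE) {
    data.frame(removed_id = ids, kept_id = rep("x", length(ids)),
               coverage_fraction = rep(0.9, length(ids)),
               identity = rep(0.95, length(ids)),
               restored = rep(restored, length(ids)),
               reason = rep("heterozygous_duplicate", length(ids)),
               stringsAsFactors = FALSE)
  }
  perfect <- evaluate_purge(dec(c("S1", "S2")), truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  nothing <- evaluate_purge(dec(character()), truth)
  expect_equal(nothing$precision, 1)
  expect_true(nothing$zero_removals)
  expect_equal(nothing$recall, 0)

  mixed <- evaluate_purge(dec(c("S1", "bogus")), truth)
  expect_equal(mixed$precision, 0.5)
  expect_equal(mixed$recall, 0.5)

  # restored removals do not count
  restored <- evaluate_purge(dec(c("S1"), restored = TRUE), truth)
  expect_true(restored$zero_removals)
})

test_that("simulations write a complete file set", {
  sim <- simulate_diploid_assembly(small_params(seed = 16))
  td <- withr::local_tempdir()
  write_simulation(sim, td)
  expect_setequal(list.files(td),
                  c("contigs.fa", "mito_ref.fa", "annotations.tsv",
                    "truth_pairs.tsv", "truth_ssrs.tsv", "truth_labels.tsv"))
  back <- read_sequences(file.path(td, "contigs.fa"))
  expect_equal(setNames(back$sequence, back$id), sim$contigs)
})

test_that("incompatible window budgets are rejected", {
  expect_error(simulation_params(genome_len = 1e5, n_haplotig_pairs = 20,
                                 contig_len_range = c(15000, 30000)),
               "incompatible")
})
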