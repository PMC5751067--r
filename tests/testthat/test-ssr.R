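test_that("unit-count thresholds follow the MISA defaults", {
  # 10 mononucleotide units qualify
  out <- find_ssrs(c(c1 = paste0("GGTC", strrep("A", 10), "GGTC")))
  expect_equal(nrow(out), 1)
  expect_equal(out$motif, "A")
  expect_equal(out$n_units, 10L)
  # (AC)5 misses the dinucleotide minimum of 6
  expect_equal(nrow(find_ssrs(c(c1 = paste0("GGT", strrep("AC", 5), "GGT")))),
               0)
  # (AGT)5 qualifies and pools to its canonical motif
  out <- find_ssrs(c(c1 = paste0("CC", strrep("AGT", 5), "CC")))
  expect_equal(out$unit_len, 3L)
  expect_equal(out$canonical_motif, canonical_motif("AGT"))
})

test_that("periodic motifs are reported at the smallest period", {
  out <- find_ssrs(c(c1 = paste0("GG", strrep("AT", 8), "GG")))
  expect_equal(out$unit_len, 2L)
  expect_equal(out$motif, "AT")
  expect_equal(nrow(out), 1)
})

test_that("rotations and reverse complements pool to one canonical motif", {
  expect_equal(canonical_motif(c("AT", "TA")), c("AT", "AT"))
  expect_equal(canonical_motif("AAT"), "AAT")
  expect_equal(canonical_motif("TAT"), "AAT")  # RC rotation
  loci <- find_ssrs(c(c1 = paste0("GG", strrep("AT", 6), "CCCGGGCCC",
                                  strrep("TA", 6), "GG")))
  expect_equal(length(unique(loci$canonical_motif)), 1)
})

test_that("detection matches the regex oracle on random sequences", {
  withr::local_seed(301)
  for (i in 1:150) {
    s <- random_dna(1000, gc = runif(1, 0.25, 0.6))
    # salt with a few tracts so matches actually occur
    if (i %% 3 == 0) {
      s <- paste0(substr(s, 1, 400), strrep("AG", sample(5:9, 1)),
                  substr(s, 401, 700), strrep("TTA", sample(4:7, 1)),
                  substr(s, 701, 1000))
    }
    got <- find_ssrs(c(x = s))
    want <- ssr_regex_oracle(s)
    expect_equal(got[, c("start", "end", "unit_len", "n_units", "motif")],
                 want[, c("start", "end", "unit_len", "n_units", "motif")],
                 ignore_attr = TRUE, info = paste("seq", i))
  }
})

test_that("compound fusion respects the interruption threshold", {
  di <- function(m) strrep(m, 6)
  p <- find_ssrs(c(c1 = paste0("GG", di("AC"), strrep("GTCA", 3),
                               di("AG"), "GG")))
  fc <- find_compound_ssrs(p, max_interruption = 100)
  expect_equal(nrow(fc$compound), 1)
  expect_equal(nrow(fc$compound$members[[1]]), 2)
  expect_equal(nrow(fc$perfect), 0)

  # ~150 bp apart with a 100 bp cap: two perfect loci survive
  # (the spacer repeats a 9-mer, longer than any scanned unit)
  far <- paste0("GG", di("AC"), strrep("GTCAATGCC", 17), di("AG"), "GG")
  p2 <- find_ssrs(c(c1 = far))
  fc2 <- find_compound_ssrs(p2, max_interruption = 100)
  expect_equal(nrow(fc2$compound), 0)
  expect_equal(nrow(fc2$perfect), 2)

  # three nearby SSRs fuse transitively
  tri <- paste0("GG", di("AC"), strrep("GTCA", 3), di("AG"),
                strrep("GTCA", 3), strrep("AAT", 5), "GG")
  fc3 <- find_compound_ssrs(find_ssrs(c(c1 = tri)), 100)
  expect_equal(nrow(fc3$compound), 1)
  expect_equal(nrow(fc3$compound$members[[1]]), 3)
})

test_that("marker selection applies the four criteria", {
  withr::local_seed(88)
  flankA <- random_dna(2500)
  flankB <- random_dna(2500)
  clean <- paste0(flankA, strrep("AC", 6), flankB)
  loci <- find_ssrs(c(c1 = clean))
  mk <- select_markers(loci, c(c1 = clean))
  expect_true(all(mk$selected))
  expect_equal(nchar(mk$flank5), 200)

  # a second SSR 1 kb away breaks the flank-exclusion criterion
  near <- paste0(flankA, strrep("AC", 6), substr(flankB, 1, 1000),
                 strrep("AAT", 5), substr(flankB, 1001, 2500))
  loci2 <- find_ssrs(c(c1 = near))
  mk2 <- select_markers(loci2, c(c1 = near))
  ac <- mk2[mk2$motif == "AC", ]
  expect_false(ac$crit_flank_ssr_free)
  expect_false(ac$selected)

  # a repeat mask over the locus breaks criterion iii
  mask <- intervals("c1", 2500, 2512)
  mk3 <- select_markers(loci, c(c1 = clean), repeat_mask = mask)
  expect_false(any(mk3$selected))
  expect_false(mk3$crit_outside_repeat[1])

  # a duplicated 5' flank breaks uniqueness
  dup <- paste0(clean, "GGGG", substr(flankA, 2301, 2500))
  mk4 <- select_markers(find_ssrs(c(c1 = dup)), c(c1 = dup))
  expect_false(any(mk4$selected))
  expect_false(all(mk4$crit_flanks_unique))

  # mono- and penta-plus loci are never eligible
  mono <- paste0(flankA, strrep("A", 12), flankB)
  mk5 <- select_markers(find_ssrs(c(c1 = mono)), c(c1 = mono))
  expect_false(any(mk5$crit_perfect_min_units))
})

test_that("removing the repeat mask can only grow the selected set", {
  withr::local_seed(404)
  s <- paste0(random_dna(2500), strrep("AC", 7), random_dna(1500),
              strrep("AGT", 6), random_dna(2500))
  loci <- find_ssrs(c(c1 = s))
  mask <- intervals(rep("c1", 2), c(2490, 4000), c(2530, 4300))
  with_mask <- select_markers(loci, c(c1 = s), repeat_mask = mask)
  without <- select_markers(loci, c(c1 = s))
  expect_true(all(with_mask$selected <= without$selected))
})

test_that("planted SSRs are recovered at exact coordinates", {
  plan <- list(list(motif = "AC", n_units = 8, count = 3),
               list(motif = "AAT", n_units = 6, count = 2),
               list(motif = "A", n_units = 12, count = 2),
               list(motif = "ACGT", n_units = 7, count = 1))
  sim <- simulate_diploid_assembly(
    simulation_params(genome_len = 4e5, n_haplotig_pairs = 2,
                      n_unique_contigs = 6, contig_len_range = c(9000, 15000),
                      n_contaminants = 0, planted_ssrs = plan, seed = 33))
  truth <- sim$truth$ssr_loci
  expect_equal(nrow(truth), 8)
  found <- find_ssrs(sim$contigs)
  key <- function(d) paste(d$contig_id, d$start, d$end, d$motif)
  expect_true(all(key(truth) %in% key(found)))
})

test_that("sub-threshold planted tracts are not reported", {
  plan <- list(list(motif = "AC", n_units = 4, count = 3),
               list(motif = "AGT", n_units = 3, count = 3))
  sim <- simulate_diploid_assembly(
    simulation_params(genome_len = 3e5, n_haplotig_pairs = 1,
                      n_unique_contigs = 4, contig_len_range = c(8000, 12000),
                      n_contaminants = 0, planted_ssrs = plan, seed = 44))
  found <- find_ssrs(sim$contigs)
  key_f <- paste(found$contig_id, found$start, found$end)
  key_t <- paste(sim$truth$ssr_loci$contig_id, sim$truth$ssr_loci$start,
                 sim$truth$ssr_loci$end)
  expect_length(intersect(key_f, key_t), 0)
})

test_that("motif frequencies count canonically and report the top type", {
  loci <- find_ssrs(c(
    c1 = paste0("GG", strrep("AAT", 5), "CCGGCCGGCC", strrep("AAT", 5),
                "CCGGTTCCAA", strrep("AC", 6), "GG")))
  tab <- motif_frequency_table(loci)
  expect_equal(tab$motifs$canonical_motif[1], "AAT")
  expect_equal(tab$motifs$count[1], 2L)
  expect_equal(tab$top_type$motif, "AAT")
  expect_equal(tab$top_type$n_units, 5L)

  empty <- motif_frequency_table(find_ssrs(c(c1 = "ACGTACGTAA")))
  expect_equal(nrow(empty$motifs), 0)
  expect_null(empty$top_type)
})
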