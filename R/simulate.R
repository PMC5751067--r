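#' Parameters for the diploid-assembly simulator
#'
#' The simulator emulates the failure mode that motivates the purge: a
#' diploid genome whose heterozygous regions are assembled twice, once per
#' haplotype, alongside single-copy contigs from homozygous regions,
#' GC-shifted foreign contigs at their own read coverage, and one
#' mitochondrion-like contig with a circular origin shift. Defaults mirror
#' the validation conditions used throughout the package: 20 redundant
#' haplotig pairs plus 20 unique contigs of 15-30 kb at 1% heterozygosity
#' (with a small-indel rate one tenth of the SNP rate), host GC 0.35, and
#' short contigs overlapping their long partner over at least 85% of their
#' length.
#'
#' @param genome_len Length of the ancestral sequence the contigs are
#'   carved from (bp).
#' @param heterozygosity Per-base SNP rate between the two haplotypes; the
#'   small-indel rate is a tenth of it (indel sizes 1-10 bp uniform).
#' @param n_haplotig_pairs Number of redundant long/short contig pairs.
#' @param n_unique_contigs Number of single-copy contigs.
#' @param contig_len_range Min/max window length (bp).
#' @param n_contaminants Number of foreign contigs.
#' @param contaminant_gc_shift GC offset of foreign contigs.
#' @param contaminant_coverage,host_coverage Read depths written to the
#'   contig annotations.
#' @param mito_len Mitochondrial genome length (bp).
#' @param read_len,read_error_rate Short-read simulation parameters.
#' @param planted_ssrs List of `list(motif=, n_units=, count=)` entries
#'   inserted into unique contigs at recorded coordinates.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(genome_len = 1500000L,
                              heterozygosity = 0.01,
                              n_haplotig_pairs = 20L,
                              n_unique_contigs = 20L,
                              contig_len_range = c(15000L, 30000L),
                              n_contaminants = 3L,
                              contaminant_gc_shift = 0.25,
                              contaminant_coverage = 5,
                              host_coverage = 46,
                              mito_len = 16000L,
                              read_len = 100L,
                              read_error_rate = 0.01,
                              planted_ssrs = list(),
                              seed = 1L) {
  p <- list(genome_len = as.integer(genome_len),
            heterozygosity = heterozygosity,
            n_haplotig_pairs = as.integer(n_haplotig_pairs),
            n_unique_contigs = as.integer(n_unique_contigs),
            contig_len_range = as.integer(contig_len_range),
            n_contaminants = as.integer(n_contaminants),
            contaminant_gc_shift = contaminant_gc_shift,
            contaminant_coverage = contaminant_coverage,
            host_coverage = host_coverage,
            mito_len = as.integer(mito_len),
            read_len = as.integer(read_len),
            read_error_rate = read_error_rate,
            planted_ssrs = planted_ssrs,
            seed = as.integer(seed))
  stopifnot(p$heterozygosity >= 0, p$heterozygosity <= 1,
            p$read_error_rate >= 0, p$read_error_rate <= 1,
            length(p$contig_len_range) == 2,
            p$contig_len_range[1] <= p$contig_len_range[2],
            all(p$contig_len_range > 0))
  budget <- (p$n_haplotig_pairs * 1.2 + p$n_unique_contigs) *
    p$contig_len_range[2]
  if (budget > p$genome_len) {
    stop("contig_len_range incompatible with genome_len: ",
         "windows would exceed the ancestral sequence")
  }
  class(p) <- "simulation_params"
  p
}

#' Simulate a fragmented diploid assembly with known truth
#'
#' @param params A [simulation_params()] list.
#' @return A list with `contigs` (named character vector), `annotations`
#'   (per-contig data frame for the contamination screen), `truth` (a list
#'   with `haplotig_pairs`, `contaminant_ids`, `mito_id`, `ssr_loci`),
#'   `mito_ref` and the `params`.
#' @export
simulate_diploid_assembly <- function(params = simulation_params()) {
  withr::with_seed(params$seed, simulate_diploid_assembly_impl(params))
}

simulate_diploid_assembly_impl <- function(p) {
  host_gc <- 0.35
  ancestral <- random_dna(p$genome_len, gc = host_gc)
  off <- 0L
  take <- function(n) {
    if (off + n > p$genome_len) stop("ancestral sequence exhausted")
    s <- substr(ancestral, off + 1L, off + n)
    off <<- off + n
    s
  }
  snp <- p$heterozygosity
  indel <- p$heterozygosity / 10

  contigs <- character()
  pairs <- NULL
  for (i in seq_len(p$n_haplotig_pairs)) {
    L <- sample(p$contig_len_range[1]:p$contig_len_range[2], 1)
    Ls <- round(L * runif(1, 0.55, 0.75))
    f <- runif(1, 0.85, 1)
    ext <- round((1 - f) * Ls)
    window <- take(L + ext)
    long_seq <- substr(window, 1L, L)
    sstart <- L - (Ls - ext)   # short spans [sstart, sstart + Ls)
    short_anc <- substr(window, sstart + 1L, sstart + Ls)
    mut <- mutate_sequence(short_anc, snp, indel)
    long_id <- sprintf("ctgL%03d", i)
    short_id <- sprintf("ctgS%03d", i)
    contigs[long_id] <- long_seq
    contigs[short_id] <- mut$seq
    pairs <- rbind(pairs, data.frame(
      kept_expected_id = long_id, removable_id = short_id,
      true_overlap_fraction = (Ls - ext) / Ls,
      true_identity = 1 - mut$n_snp / nchar(short_anc),
      stringsAsFactors = FALSE))
  }

  unique_ids <- sprintf("ctgU%03d", seq_len(p$n_unique_contigs))
  for (id in unique_ids) {
    L <- sample(p$contig_len_range[1]:p$contig_len_range[2], 1)
    contigs[id] <- take(L)
  }

  ssr_truth <- plant_ssrs(contigs, unique_ids, p$planted_ssrs)
  contigs <- ssr_truth$contigs

  contam_ids <- character()
  if (p$n_contaminants > 0) {
    contam_ids <- sprintf("ctgC%03d", seq_len(p$n_contaminants))
    for (id in contam_ids) {
      L <- sample(5000:15000, 1)
      contigs[id] <- random_dna(L, gc = host_gc + p$contaminant_gc_shift)
    }
  }

  mito_ref <- random_dna(p$mito_len, gc = 0.20)
  shift <- sample(seq_len(p$mito_len - 1L), 1)
  mito_id <- "ctgM001"
  contigs[mito_id] <- paste0(substr(mito_ref, shift + 1L, p$mito_len),
                             substr(mito_ref, 1L, shift))

  ids <- names(contigs)
  host <- !(ids %in% c(contam_ids, mito_id))
  gc_frac <- vapply(contigs, function(s) {
    comp <- base_composition(setNames(s, "x"))
    unname((comp["G"] + comp["C"]) / sum(comp))
  }, 0)
  annotations <- data.frame(
    contig_id = ids,
    length = unname(nchar(contigs)),
    gc = unname(gc_frac),
    read_coverage = ifelse(ids %in% contam_ids, p$contaminant_coverage,
                    ifelse(ids == mito_id, p$host_coverage * 20,
                           p$host_coverage * runif(length(ids), 0.9, 1.1))),
    best_hit_taxon = ifelse(ids %in% contam_ids, "Proteobacteria",
                     ifelse(runif(length(ids)) < 0.5, "Arthropoda",
                            NA_character_)),
    has_transcript_evidence = host & runif(length(ids)) < 0.9,
    has_busco_gene = host & runif(length(ids)) < 0.5,
    stringsAsFactors = FALSE)
  annotations$best_hit_taxon[annotations$contig_id == mito_id] <- "Arthropoda"

  list(contigs = contigs, annotations = annotations,
       truth = list(haplotig_pairs = pairs,
                    contaminant_ids = contam_ids,
                    mito_id = mito_id,
                    ssr_loci = ssr_truth$truth),
       mito_ref = setNames(mito_ref, "mito_ref"),
       params = p)
}

# insert perfect SSR tracts into the named contigs at recorded coordinates;
# guard bases on both sides stop the runs from extending, so detection
# recovers the exact planted interval
plant_ssrs <- function(contigs, host_ids, planted) {
  truth <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      n_units = integer(), stringsAsFactors = FALSE)
  if (length(planted) == 0) return(list(contigs = contigs, truth = truth))
  occupied <- lapply(setNames(host_ids, host_ids),
                     function(...) data.frame(start = integer(),
                                              end = integer()))
  for (entry in planted) {
    motif <- toupper(entry$motif)
    u <- nchar(motif)
    if (u < 1 || u > 7) stop("planted SSR motif must be 1-7 bp")
    if (is_reducible_motif(motif)) {
      stop("planted SSR motif must not itself be periodic: ", motif)
    }
    count <- if (is.null(entry$count)) 1L else entry$count
    for (r in seq_len(count)) {
      tract <- strrep(motif, entry$n_units)
      len <- nchar(tract)
      placed <- FALSE
      for (attempt in 1:50) {
        id <- sample(host_ids, 1)
        cl <- nchar(contigs[[id]])
        if (cl < len + 600) next
        pos <- sample.int(cl - len - 600L, 1) + 300L  # 0-based start
        occ <- occupied[[id]]
        if (any(occ$end + 50 > pos & occ$start - 50 < pos + len)) next
        s <- contigs[[id]]
        left <- guard_base(substr(motif, u, u))
        right <- guard_base(substr(motif, 1L, 1L))
        substr(s, pos, pos) <- left                 # 1-based pos == 0-based pos-1
        substr(s, pos + 1L, pos + len) <- tract
        substr(s, pos + len + 1L, pos + len + 1L) <- right
        contigs[[id]] <- s
        occupied[[id]] <- rbind(occ, data.frame(start = pos, end = pos + len))
        truth <- rbind(truth, data.frame(
          contig_id = id, start = pos, end = pos + len, motif = motif,
          n_units = entry$n_units, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted SSR (", motif, ")")
    }
  }
  list(contigs = contigs, truth = truth)
}

guard_base <- function(avoid) {
  setdiff(c("A", "C", "G", "T"), avoid)[1]
}

is_reducible_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1)) {
    if (u %% d != 0) next
    unit <- substr(motif, 1, d)
    if (strrep(unit, u / d) == motif) return(TRUE)
  }
  FALSE
}

#' Generate a random DNA sequence
#'
#' @param n Length in bp.
#' @param gc GC fraction.
#' @return A single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# mutate a haplotype: substitutions at snp_rate, small indels (1-10 bp,
# insertion or deletion with equal probability) at indel_rate
mutate_sequence <- function(s, snp_rate, indel_rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sub_idx <- which(runif(n) < snp_rate)
  for (i in sub_idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  ev_idx <- sort(which(runif(n) < indel_rate), decreasing = TRUE)
  for (i in ev_idx) {
    size <- sample(1:10, 1)
    if (runif(1) < 0.5) {
      chars <- append(chars, sample(c("A", "C", "G", "T"), size,
                                    replace = TRUE), after = i)
    } else {
      drop <- i:min(i + size - 1L, length(chars))
      chars <- chars[-drop]
    }
  }
  list(seq = paste(chars, collapse = ""), n_snp = length(sub_idx),
       n_indel = length(ev_idx))
}

#' Simulate error-bearing short reads from contigs
#'
#' Reads are drawn uniformly (contigs weighted by length) with a random
#' strand; substitution errors occur independently at `error_rate`, with
#' constant Q40 qualities at correct bases and Q10 at error positions. The
#' expected base yield is `coverage * total_len` within 1%.
#'
#' @param contigs Sequences (any container accepted by the package).
#' @param coverage Target mean depth.
#' @param read_len Read length (must not exceed the shortest contig).
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @return A record data frame (`id`, `sequence`, `quality` as Phred+33
#'   strings) suitable for [write_sequences()] and [count_kmers()].
#' @export
simulate_reads <- function(contigs, coverage, read_len, error_rate = 0,
                           seed = 1L) {
  seqs <- as_sequences(contigs)
  if (read_len > min(nchar(seqs))) {
    stop("read_len exceeds the shortest contig")
  }
  withr::with_seed(seed, {
    lens <- nchar(seqs)
    n_reads <- round(coverage * sum(lens) / read_len)
    ctg <- sample.int(length(seqs), n_reads, replace = TRUE,
                      prob = lens - read_len + 1)
    pos <- floor(runif(n_reads) * (lens[ctg] - read_len + 1)) + 1L
    reads <- substring(unname(seqs)[ctg], pos, pos + read_len - 1L)
    minus <- runif(n_reads) < 0.5
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    qual <- rep(strrep("I", read_len), n_reads)   # Q40
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_len, error_rate)
      for (i in which(n_err > 0)) {
        p <- sample.int(read_len, n_err[i])
        r <- reads[i]; q <- qual[i]
        for (j in p) {
          substr(r, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(r, j, j)), 1)
          substr(q, j, j) <- "+"                  # Q10
        }
        reads[i] <- r; qual[i] <- q
      }
    }
    out <- data.frame(id = sprintf("read%07d", seq_len(n_reads)),
                      sequence = reads, stringsAsFactors = FALSE)
    out$quality <- qual
    out
  })
}

#' Score purge decisions against the simulation truth
#'
#' A true positive is a non-restored removal whose removed contig is one of
#' the truth's removable haplotigs. With no removals at all, precision is
#' reported as 1 with a flag.
#'
#' @param decisions Decision table from [purge_assembly()].
#' @param truth Truth list from [simulate_diploid_assembly()].
#' @return A list with `precision`, `recall`, `tp`, `n_removed`, `n_true`
#'   and `zero_removals`.
#' @export
evaluate_purge <- function(decisions, truth) {
  removed <- decisions$removed_id[!decisions$restored]
  truth_ids <- truth$haplotig_pairs$removable_id
  tp <- sum(removed %in% truth_ids)
  n_removed <- length(removed)
  n_true <- length(truth_ids)
  list(precision = if (n_removed == 0) 1 else tp / n_removed,
       recall = if (n_true == 0) 1 else tp / n_true,
       tp = tp, n_removed = n_removed, n_true = n_true,
       zero_removals = n_removed == 0)
}

#' Write a simulation to disk
#'
#' Emits `contigs.fa`, `mito_ref.fa`, `annotations.tsv` and the truth
#' tables (`truth_pairs.tsv`, `truth_ssrs.tsv`, `truth_labels.tsv`).
#'
#' @param sim Result of [simulate_diploid_assembly()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sequences(sim$contigs, file.path(dir, "contigs.fa"))
  write_sequences(sim$mito_ref, file.path(dir, "mito_ref.fa"))
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(sim$annotations, "annotations.tsv")
  tsv(sim$truth$haplotig_pairs, "truth_pairs.tsv")
  tsv(sim$truth$ssr_loci, "truth_ssrs.tsv")
  tsv(data.frame(contig_id = c(sim$truth$contaminant_ids,
                               sim$truth$mito_id),
                 label = c(rep("contaminant",
                               length(sim$truth$contaminant_ids)), "mito")),
      "truth_labels.tsv")
  invisible(dir)
}
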