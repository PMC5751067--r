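---
title: "Curating heterozygous genome assemblies with asmcurate"
author: "asmcurate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating heterozygous genome assemblies with asmcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmcurate)
```

## The problem

A long-read assembler confronted with a highly heterozygous diploid genome
tends to collapse homozygous regions into single contigs while emitting the
two haplotypes of divergent regions as *separate* contigs. The resulting
assembly is inflated — often by hundreds of megabases — and redundant: for
many regions it carries a long "primary" contig and a shorter alternative
haplotype contig (a haplotig) that represents the same locus. Downstream
analyses that assume a haploid reference (gene counts, repeat fractions,
population mapping) are biased until the redundant haplotigs are removed.

`asmcurate` implements the post-assembly computations this curation needs:

1. a k-mer spectrum genome-size estimate that quantifies the inflation,
2. whole-assembly self-alignment and coverage-based haplotig purging,
3. mitochondrial and taxon-annotated GC-coverage (blob plot) contamination
   screens,
4. short-read cleaning, microsatellite (SSR) detection and marker
   selection, and assembly summary statistics,
5. a diploid assembly simulator with truth labels so that every stage can
   be validated without external data.

## Genome size from the k-mer spectrum

For a read set with total k-mer count $K_{total}$, error-like k-mer count
$K_{err}$ (multiplicities at or below `error_multiplicity_max`, default 1)
and homozygous-coverage peak depth $D$, the genome size is estimated as

$$G = \frac{K_{total} - K_{err}}{D}.$$

`count_kmers()` builds the spectrum in compiled code (canonical
Jellyfish-style counting by default; windows containing `N` are skipped).
`find_peak_depth()` locates $D$ as the multiplicity maximising the distinct
k-mer count beyond the error valley — the first local minimum at
multiplicity `>= min_valley_search` (default 2). Ties break toward the
smaller multiplicity, and a histogram that decreases over its whole support
has no coverage peak and raises an error rather than guessing. $G$ is
rounded half-up to integer base pairs; megabase figures are reported to 0
decimals.

```{r}
est <- genome_size_from_counts(K_total = 37238236952,
                               K_error = 1144064507, D = 46)
est
```

A heterozygous spectrum can be bimodal (a half-depth heterozygous peak next
to the homozygous one); `estimate_genome_size()` therefore accepts an
operator-supplied `D` that overrides the automatic peak.

## Self-alignment and haplotig purging

### Exact-anchor self-alignment

`anchor_matches()` is a built-in substitute for an external whole-genome
self-aligner. Canonical 21-mers (configurable via `anchor_k`) occurring at
most `max_anchor_occurrence` times in the assembly are anchors; maximal
runs of consecutive co-diagonal anchors shared by two contigs become
alignment blocks, and blocks spanning fewer than `min_block_len` bp
(default 100) are dropped as noise. The matcher is exact by design: at 1%
haplotype divergence an exact block ends at every variant, so one
homologous region appears as dozens of fragments. That fragmentation is not
a defect to be papered over at the alignment stage — it is the signal the
chaining stage is built to integrate. Canonical anchors give reverse-strand
detection without a second pass; matches of a contig against itself are not
emitted.

### Chaining by weighted longest increasing subset

`chain_lis()` clusters the fragments of one contig pair (and strand) with a
dynamic program: it selects the subset of blocks, strictly increasing in
both query and target coordinates, that maximises total matched bases.
Selected blocks form a chain — one clustered "larger match"; leftovers are
re-chained until nothing remains or the best chain weighs less than
`min_block_len`. Two numerical choices matter:

* **Tie-breaking.** Among equal-weight chains the program prefers the
  smaller total junction gap (query gap plus target gap summed over
  junctions), then the chain whose first block starts earlier on the query.
  This keeps the result deterministic and prefers compact, co-diagonal
  chains over chains that jump across the target.
* **Identity bookkeeping.** A chain's `span_identity` is total matched
  bases over the summed per-block spans — the accuracy *within aligned
  segments*. `merge_adjacent_blocks()` then fuses consecutive blocks whose
  gaps on both sequences are at most `max_chain_gap` (default 500 bp),
  summing matched bases; a fused block's identity is the matched-weighted
  mean of its parts, and the chain keeps its pre-merge span identity.
  Counting bridged heterozygous gaps as mismatches would conflate coverage
  with identity and defeat the restore rule below.

### Pair coverage and the 80% rule

`pair_coverage()` projects each chain's span — first block start to last
block end on the *shorter* contig — and takes the union. The chain span,
not the union of individual blocks, is the covering unit: chaining exists
precisely because heterozygous breaks inside a co-linear run belong to one
homologous region, and the extended gapped alignments of production
aligners span those breaks the same way. The trade-off is deliberate: if
two genuinely distinct duplications on one contig pair are chained across
an unrelated middle section, coverage is overstated — which is exactly the
class of error the per-removal dot-plot export and the operator restore
list exist to catch.

`purge_assembly()` processes pairs in decreasing order of the long contig's
length and discards the short contig of any pair whose coverage fraction
reaches `coverage_removal_threshold` (default 0.80), with two guards that
are design choices rather than published rules:

* **No cascade.** A contig removed earlier in the pass cannot itself cause
  removals. This makes the output order-independent and prevents a chain
  reaction that loses both haplotypes of a region.
* **Mechanised review.** Every removal whose pair identity falls below
  `min_restore_identity` (default 0.90; the published demonstration pair
  passed at 0.94) is automatically restored and flagged. The manual
  dot-plot audit of the original workflow survives as the exported
  per-removal TSV dot plots plus an operator restore list.

Mitochondrial contigs are flagged when at least 80% of their length aligns
to mitochondrial references at E-value below `1e-5`; blob-plot screening
discards contigs with read coverage below 10, or with a best database hit
outside the target clade and neither transcript evidence nor a conserved
single-copy orthologue. Contigs with no best hit are treated as in-clade —
absence of a database hit is not evidence of contamination.

## Read cleaning

`clean_read()` applies the five-rule Illumina policy in a fixed order:
adapter screen (exact substring, whole-read discard), unconditional
trimming of 2 bases at the 5' end and 3 at the 3' end, then the N-fraction
(>10%) and low-quality-fraction (>50% of bases at Q<=5) filters evaluated
on the post-trim sequence with strict inequalities. The trimming counts are
fixed, not quality-conditional: the rule states counts, and an
unconditional trim is reproducible. PCR duplicates are removed per pair on
the `(R1, R2)` sequence tuple only — duplicates share sequence, not quality
strings — keeping the first occurrence.

## SSR detection and marker selection

`find_ssrs()` reports maximal perfect tandem repeats with unit lengths 1-7
at the MISA thresholds (10 units for mono-, 6 for di-, 5 for tri- through
hepta-nucleotide motifs), whole units only, smallest period first (ATAT is
2 x AT), leftmost and non-overlapping per unit length. Motifs pool under a
canonical form: the lexicographically smallest rotation of the motif or its
reverse complement, while the raw motif is retained so that reporting can
distinguish, say, an (AAT)5 locus from its TAT reading frame.
`find_compound_ssrs()` fuses perfect loci separated by at most
`compound_max_interruption` bp (default 100, MISA's convention) into
compound loci.

`select_markers()` applies four criteria: (i) perfect di-/tri-/tetra-
nucleotide loci with at least 6/5/5 units (mono and penta-plus motifs are
not eligible); (ii) no *other* SSR within 2 kb of either boundary — read as
"no neighbour in the flanking windows", since the locus trivially occupies
its own span; (iii) outside the repeat mask; (iv) each 200-bp flank occurs
exactly once in the assembly as an exact match on either strand, with
flanks truncated by a contig end failing outright. Exact full-length flank
search keeps criterion (iv) deterministic and oracle-checkable; a
mismatch-tolerant mapping mode is out of scope. The expensive criterion
(iv) is evaluated only for candidates that already pass (i)-(iii).

## Summary statistics

`assembly_stats()` computes N50/N90 by the cumulative-length convention
(length and 1-based rank of the contig at which the sorted cumulative sum
first reaches 50%/90% of the total) and GC over called bases only.
`repeat_summary()` and `annotation_summary()` reproduce percentage tables
with half-up rounding to two decimals; repeat classes are trusted as
disjoint inputs, overlap warns rather than errors, and an explicit `Total`
entry supplies the non-redundant union total where class masks overlap
(RepeatMasker-style summaries report such totals). `consensus_qv()` converts
a homozygous-variant rate to `QV = floor(-10 log10 rate)` — floored, because
the value is reported as an integer class — capped at 60, with zero variants
reporting the cap plus a flag. `genome_size_concordance()` reports assembly
length over estimated genome size to one decimal, unclamped.

## The simulator: what it emulates, and what it does not

`simulate_diploid_assembly()` builds the failure mode the purge targets: an
ancestral sequence (GC 0.35, matching a typical AT-rich insect genome) is
carved into non-overlapping windows; each haplotig pair emits the window as
a long contig (haplotype A) and a mutated sub-window as a short contig
(haplotype B, SNPs at the `heterozygosity` rate and 1-10 bp indels at one
tenth of it — a typical ratio for insect heterozygosity, and the indels
deliberately shift alignment diagonals), with the short contig's overlap
fraction drawn uniformly from [0.85, 1]. Unique contigs come from
homozygous windows; contaminants are GC-shifted (+0.25) random sequences
labelled with foreign taxa at their own read coverage (5 by default, below
the blob floor); one AT-rich 16 kb mitochondrion-like contig is emitted as
a rotation of its reference, emulating a circular origin shift. Planted
SSR tracts carry guard bases on both sides so detection must recover the
exact planted interval. Read simulation draws uniform positions and
strands, substitution errors only, constant Q40/Q10 qualities.

Default scale: 20 haplotig pairs plus 20 unique contigs of 15-30 kb on a
1.5 Mb ancestral sequence, heterozygosity 0.01, host coverage 46. These
sizes keep a full simulate-align-purge cycle at a few seconds while still
producing dozens of fragmentary blocks per pair for the chaining stage;
validation runs use 20 independent seeds, and the k-mer recovery check uses
a 1 Mb genome at depth 40.

What passing tests on this generator do **not** show: real assemblies break
at repeats (the simulator plants none beyond SSR tracts), PacBio consensus
errors are not substitution-only, coverage labels are written into the
annotations rather than derived from read mapping, true haplotype
divergence is not uniform along chromosomes, and real contaminant taxa are
not a single foreign label. The generator validates the decision machinery,
not the upstream assembler or aligner.

## Known limitations

* The internal self-aligner is exact; a sustained divergence cluster (a
  few hundred bases without any 100-bp exact stretch) inside an otherwise
  chainable region is bridged by the chain span but contributes no matched
  bases — on data far more divergent than a few percent, external MUMmer or
  Last tables (via `parse_alignment_table()`) are the better evidence and
  pool transparently with the internal blocks.
* Coverage evidence from multiple aligners is pooled by union before
  chaining; no per-source weighting is attempted.
* The blob screen approximates a full best-sum-order taxonomy rule with a
  single best-hit field per contig.
* Flank uniqueness for markers is exact-match only; primer design is out
  of scope.
* A published rate/QV pair that is internally inconsistent cannot be
  reproduced by the stated formula; `consensus_qv()` computes from the rate
  and does not special-case it.
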