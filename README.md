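# asmcurate

Post-assembly curation of heterozygous genome assemblies, for genome
projects that assemble a diploid organism with substantial haplotype
divergence and end up with an inflated, redundant contig set. Long-read
assemblers collapse homozygous regions but emit the two haplotypes of
divergent regions as separate contigs, so the assembly carries both a long
primary contig and a shorter alternative-haplotype contig (a *haplotig*)
for many loci. `asmcurate` detects and removes those haplotigs, screens out
mitochondrial and contaminant contigs, and provides the surrounding
bookkeeping a genome report needs — k-mer genome-size estimation, read
cleaning, SSR marker selection, and assembly statistics — plus a synthetic
diploid simulator with truth labels so the whole pipeline is testable
offline.

## Methods at the core

**Genome size from the k-mer spectrum.** With total k-mer count K_total,
error k-mer count K_err (multiplicity ≤ 1 by default) and coverage peak
depth D from the spectrum,

    G = (K_total − K_err) / D.

Counting is canonical (strand-collapsed) and runs in compiled code; the
peak is the argmax of distinct k-mer counts beyond the first local minimum
of the histogram (the error valley).

**Haplotig purging by self-alignment.** A built-in exact-anchor matcher
aligns every contig pair (canonical 21-mer anchors, maximal co-diagonal
runs, blocks ≥ 100 bp); because heterozygosity fragments exact alignments,
the blocks of each pair are clustered by a maximum-weight
longest-increasing-subset dynamic program (weight = matched bases), and
adjacent blocks with gaps ≤ 500 bp on both sequences are merged. Each chain
counts as one match; the fraction of the shorter contig covered by chain
spans drives the rule: *coverage ≥ 80% removes the short contig*, processed
in decreasing order of long-contig length, with removals below identity
0.90 automatically restored and every removal exporting a dot-plot TSV for
review. External MUMmer `show-coords` or BLAST/Last tabular alignments can
be pooled with the internal blocks via `parse_alignment_table()`.
Mitochondrial contigs (≥ 80% aligned to a mito reference at E < 1e-5) and
blob-plot contaminants (coverage < 10, or foreign best hit without
transcript/orthologue evidence) are screened afterwards.

**SSR markers.** MISA-style perfect microsatellite detection (unit lengths
1–7 at minimum unit counts 10/6/5/5/5/5/5), compound fusion across ≤ 100 bp
interruptions, and four-criterion marker selection: perfect di/tri/tetra
loci with ≥ 6/5/5 units, no neighbouring SSR within 2 kb, outside the
repeat mask, and both 200-bp flanks unique in the assembly.

## Worked example

```r
library(asmcurate)

# genome size from published 17-mer counts
est <- genome_size_from_counts(K_total = 37238236952,
                               K_error = 1144064507, D = 46)
est
#> Genome size estimate: 784,655,923 bp (~785 Mb)
#>   K_total = 37,238,236,952, K_error = 1,144,064,507 (m <= 1), D = 46
genome_size_concordance(760416098, est)
#> [1] 96.9

# purge a simulated heterozygous assembly with known truth
sim <- simulate_diploid_assembly(simulation_params(seed = 42))
res <- purge_pipeline(sim$contigs, annotations = sim$annotations)
head(res$decisions[, c("removed_id", "kept_id", "coverage_fraction",
                       "identity", "restored")], 3)
#>   removed_id kept_id coverage_fraction identity restored
#> 1    ctgS019 ctgL019            0.8420        1    FALSE
#> 2    ctgS005 ctgL005            0.8661        1    FALSE
#> 3    ctgS015 ctgL015            0.8849        1    FALSE
evaluate_purge(res$decisions, sim$truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1

assembly_stats(res$kept)
#> Assembly statistics
#>   contigs: 41  total: 950,415 bp  mean: 23,181 bp
#>   N50: 24,739 bp (rank 18)  N90: 16,085 bp (rank 36)
#>   longest: 29,963 bp  GC: 34.80%
```

The 20 simulated haplotigs are removed with precision and recall 1.0; the
41 survivors are the 20 long haplotypes, the 20 unique contigs and the
mitochondrion-like contig (removable via `mito_hits`), while the three
GC-shifted contaminants fall to the blob screen.

A thin command-line wrapper ships in `inst/cli/asm-curate.R`:

```sh
Rscript inst/cli/asm-curate.R simulate --out-dir sim --seed 3
Rscript inst/cli/asm-curate.R purge --contigs sim/contigs.fa \
    --annotations sim/annotations.tsv --out kept.fa
Rscript inst/cli/asm-curate.R ssr --contigs kept.fa --markers markers.tsv
```

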