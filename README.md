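# spliceRIP

Alternative-splicing event detection, RIP-seq peak calling and their
integration, for studies of RNA-binding proteins (RBPs) that combine
two-condition RNA-seq with RIP-seq (IP versus total-lysate input). The
package is aimed at analysts who want the full computational chain of such
a study — expression, splicing, binding, and the bound-versus-regulated
overlap — as tested, reusable R functions operating on the standard
formats (SAM alignments, GTF annotation, FASTA genome), plus a seeded
synthetic-data generator with machine-readable ground truth for validating
every stage.

## What it computes

**Expression.** Unique-fragment counts per gene; FPKM
(`count × 10⁹ / (libraryTotal × exonUnionLength)`); a hierarchically
clustered Pearson correlation matrix of samples; differential expression
by an exact two-sided binomial test on condition-pooled counts with
library-size offsets, reported at |FC| ≥ 2 and BH-adjusted p ≤ 0.05.

**Splicing.** Classification of splice-junction evidence into ten event
types — exon skipping (ES), cassette exon (CE, ≥ 2 exons skipped),
alternative 5'/3' splice sites (A5SS, A3SS), their composites with
skipping (A5SS&ES, A3SS&ES), mutually exclusive exons (MXE) and their
first/last-exon variants (5pMXE, 3pMXE), and intron retention (IR,
requiring ungapped reads across both exon–intron boundaries). Each event
is quantified per sample by the AS ratio `alt / (alt + model)` of
junction-supporting reads, and regulated events (RASEs) are called with a
Student's t-test across replicates at p ≤ 0.05 and |Δratio| ≥ 0.2.

**Binding peaks.** Reads overlapping by ≥ 1 bp are clustered into
candidate peaks scored by maximum depth; each gene's null distribution of
maximum peak height comes from 500 uniform re-placements of the same reads
within the gene span; peaks with empirical `p = (1 + #{null ≥ h})/(1+500)
< 0.05` are kept, IP peaks overlapping significant input peaks are
removed, and replicates are intersected.

**Integration.** Read/peak distributions over genomic feature classes
(5'UTR, CDS, 3'UTR, noncoding exon, intron, intergenic), binding-target
gene sets, their overlap with regulated-splicing genes, and k-mer
enrichment in peak sequences against resampled length-matched background
windows.

## Worked example

Simulate a small two-condition experiment with planted signals and run the
whole pipeline against it:

```r
library(spliceRIP)

cfg <- simulation_config(seed = 42, n_genes = 60, genome_length = 6e5,
                         rnaseq_depth = 6e4, rip_depth = 4e4)
sim <- simulate_experiment(cfg, file.path(tempdir(), "demo"))
#> sim_experiment: 60 genes on 6e+05 bp; 6 planted DEGs, 15 planted AS
#> events, 9 planted peaks (+3 shared artifacts)

res <- run_pipeline(sim)
sum(res$degs$significant)        # 6   -- the six planted fold-change genes
nrow(res$events)                 # 15  -- all planted events, correct types
sum(res$rases$significant)       # 14  -- 14/15 ratio shifts pass both gates
length(res$targets)              # 9   -- genes bound in both IP replicates
head(res$kmers, 1)
#>    kmer       f_obs        f_bg       sd_bg    z
#> 1 GCGCG 0.00080083 4.48466e-05 5.86931e-05 9.44

evaluate_truth(sim, res)[c("deg_recall", "rase_recall", "peak_recall",
                           "artifact_removed", "motif_rank")]
#> $deg_recall 1  $rase_recall 0.93  $peak_recall 1
#> $artifact_removed 1  $motif_rank 1
```

The numbers mean: every planted 4-fold expression change was recovered at
the |FC| ≥ 2 / FDR ≤ 0.05 gates; all fifteen planted splicing events were
detected with their intended type and fourteen passed the regulated-event
gates (one sat just under the support threshold in one replicate); every
planted 10× peak was called in both IP replicates while all shared
IP/input artifact peaks were subtracted; and the GC-rich 5-mer written
into the peaks ranks first among all 1024 k-mers.

`simulate_experiment()` writes `genome.fa`, `annotation.gtf`, one SAM per
library, and `truth_*.tsv` tables to the output directory, so each stage
can equally be driven from files via `parse_gtf()`, `read_alignments()`,
and the stage functions (`count_fragments()`, `detect_events()`,
`call_peaks()`, `kmer_enrichment()`, ...).

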