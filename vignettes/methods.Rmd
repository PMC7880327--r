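---
title: "Splicing events, binding peaks and their integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing events, binding peaks and their integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceRIP)
```

## What this package computes

spliceRIP implements the computational core of a common RNA-binding-protein
(RBP) study design: two-condition RNA-seq (for example, control versus
RBP-overexpressing cells) analysed for differential expression and for
regulated alternative splicing, combined with RIP-seq (IP versus
total-lysate input) analysed for binding peaks, and an integrative layer
that asks whether the bound transcripts are the ones whose splicing
changes. Every stage runs on aligned spliced reads (SAM), a gene annotation
(GTF) and a genome (FASTA). A seeded synthetic-data generator produces all
three with planted, machine-readable ground truth, so the whole pipeline is
testable end to end without any external data.

## Expression and differential expression

Fragments are counted per gene when all aligned blocks fall inside the gene
span on the matching strand; fragments compatible with more than one gene
are left unassigned. Expression is reported as FPKM,

$$\mathrm{FPKM}(g) = \frac{10^9 \, c_g}{N \, \ell_g},$$

with $c_g$ the fragment count, $N$ the library total and $\ell_g$ the
exon-union length of the gene — the conservative resolution of
transcript-level length ambiguity. Sample similarity is summarised by the
Pearson correlation matrix of FPKM columns, ordered by average-linkage
clustering on $1 - r$.

Differential expression is called per gene from the condition-pooled counts
with an exact two-sided binomial test against the library-size proportion —
the exact conditional test for a Poisson rate ratio. Fold change is
computed from library-size-normalised mean counts with a pseudocount of one
fragment, and a gene is reported as differentially expressed when
$|\mathrm{FC}| \ge 2$ and the Benjamini–Hochberg adjusted p-value is at
most 0.05. The count test is deliberately simple: the stage's contract is
the pair of thresholds, not any particular dispersion machinery, and the
generator's Poisson law matches the test's assumptions exactly. With real
(overdispersed) RNA-seq counts this test is anti-conservative and a
negative-binomial test should be substituted; the surrounding thresholds
and reporting are unchanged.

## Alternative splicing: the event grammar

Splicing evidence is the set of junction reads: alignments whose CIGAR
contains an N gap. Each gap defines a junction with exact donor and
acceptor coordinates (no fuzzy matching), counted once per read per
junction. Against each gene's annotated exon boundaries, the observed
junctions of the gene are classified into ten event types:

| type | pattern |
|------|---------|
| ES | skip junction versus an inclusion chain over exactly one exon, sharing both outer anchors |
| CE | the same with two or more consecutive skipped exons (cassette) |
| A5SS / A3SS | two junctions sharing one anchor whose alternative boundaries lie in overlapping exons (an alternative end of the same exon); naming follows the transcription direction |
| A5SS&ES / A3SS&ES | a one-exon skip whose outer anchor is shifted to an alternative boundary of the flanking exon |
| MXE | two disjoint exons, each supported from a common upstream anchor and to a common downstream anchor, never joined to each other |
| 5pMXE / 3pMXE | the mutual-exclusion pattern at the first/last exon position (no junctions on the outer side) |
| IR | a junction whose intron has ungapped reads crossing both exon–intron boundaries |

The patterns are mutually exclusive by construction: skip-chain events
require exact or singly-shifted anchor matches over annotated exons,
mutual-exclusion events require *disjoint* exons, and alternative-boundary
events require *overlapping* exons. One deliberate design choice: ES and
CE are distinguished by the number of consecutively skipped exons (one
versus several). The alternative convention — calling an event CE whenever
the skip isoform is annotated — collapses as soon as both isoforms of a
planted event are annotated, which is exactly the situation the generator
creates, so it cannot yield a mutually exclusive grammar here.

Intron retention needs coverage evidence, not just junctions: a boundary is
considered crossed when an ungapped read extends at least `anchor = 5`
bases on both sides of it, and both boundaries must be crossed. This makes
IR detection impossible from a junction table alone, which is why
`detect_events()` takes the (pooled) alignments as an optional argument.

## Quantification and regulated events

For each event and sample, the model count is the mean supporting-read
count over the model junctions and the alternative count the mean over the
alternative junctions (for IR, the mean number of ungapped reads crossing
the two boundaries). The AS ratio is

$$r = \frac{\mathrm{alt}}{\mathrm{alt} + \mathrm{model}},$$

the standard junction-ratio convention; it is symmetric, in the sense that
swapping the model and alternative labels maps $r \mapsto 1 - r$ and leaves
the downstream test invariant. Means rather than sums keep multi-junction
forms (inclusion chains, mutually exclusive exon pairs) on the same scale
as single junctions. The ratio is reported only when the summed raw
support in that sample reaches `min_support = 10` reads; below that the
sample is NA for the event.

Regulated events are called with a two-sample Student's t-test (pooled
variance) on the per-replicate ratios, requiring at least two defined
ratios per condition. An event is significant when the raw p-value is at
most 0.05 **and** the absolute difference of condition mean ratios is at
least 0.2. A Benjamini–Hochberg column is emitted alongside for users who
prefer an FDR gate; the flag itself uses the raw-p rule, and with both
columns present either convention can be applied downstream.

## Peak calling with a permutation null

RIP peaks are called per library. Reads assigned to a gene are clustered by
transitive $\ge$ 1 bp overlap (bookended reads do *not* merge); each
cluster is a candidate peak whose height is its maximum per-base depth
(a read-count height is available behind the `height` argument). The null
model re-places the same number of reads, with the same lengths, uniformly
at random within the gene span, 500 times by default, recording each
simulation's maximum height; placement ignores exon structure, matching a
gene-level (not transcript-level) null. The empirical p-value uses add-one
smoothing,

$$p = \frac{1 + \#\{\mathrm{sim} : \max_{\mathrm{null}} \ge h\}}{1 + n_{\mathrm{sim}}},$$

so it is never zero, and candidates with $p < 0.05$ are significant. The
inner placement loop is compiled (Rcpp) and uses R's RNG, so a single
`set.seed()` reproduces the entire peak set bit for bit. IP and input
libraries are assessed separately; an IP peak is then removed if it
overlaps any significant input peak by at least 1 bp on the same strand,
and replicates are called independently and intersected.

Two properties worth knowing at high read density: (i) when mean coverage
is high, 1 bp-overlap clustering merges most of a gene into one cluster, so
peak intervals approach gene spans — peak *calls* remain calibrated
because the height, not the width, is tested; (ii) an input library with no
true peaks still yields significant input peaks for about 5% of genes
(that is what a calibrated 5% test does), and subtracting them removes the
corresponding IP peaks regardless of their merit. Both behaviours are
inherent to the method and are visible in the synthetic experiments: the
retained-peak recall runs a few percent below the called-peak recall.

## Integration

Each gene span is tiled into 5'UTR / CDS / 3'UTR (coding transcripts, split
by the CDS span with strand deciding which side is 5'), noncoding exons
(transcripts without a CDS) and introns; conflicts between transcripts are
resolved by the precedence CDS > 5'UTR > 3'UTR > NC exon > intron, so
translated sequence wins. Reads and peaks are assigned one class by
majority overlap with ties broken by the same precedence. Binding targets
are the genes carrying at least one retained peak in both IP replicates,
and the bound set is intersected with the genes of significant regulated
events.

Motif signal in retained peaks is summarised by k-mer enrichment (a
light-weight stand-in for a full motif-discovery pipeline): k-mer
frequencies in the peak sequences (minus-strand peaks reverse-complemented
first, so k-mers are read in the transcribed orientation) are compared with
length-matched windows resampled from expressed gene spans outside peaks.
The z-score is $(f_{\mathrm{obs}} - \bar f_{\mathrm{bg}}) /
\mathrm{sd}(f_{\mathrm{bg}})$ over `n_bg = 50` resamples, with the
denominator floored at the binomial counting error of the observed window
total so that k-mers rare in the background cannot acquire degenerate
scores. Full peak sequences are used rather than summits, since cluster
summits are not defined sharply under 1 bp-overlap clustering.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
sequencing chemistry. Its defaults are the study-scale conditions used by
the acceptance checks:

* 200 non-overlapping multi-exon genes (3–6 exons of 150–300 bp, introns
  200–500 bp) on both strands of a 2 Mb chromosome; 20% of constitutive
  genes noncoding. Base composition is AT-rich (30% G+C), as in
  transcribed mammalian sequence, which is the background against which a
  GC-rich motif is meaningful.
* log-normal baseline expression (sdlog 0.8) shared by all libraries;
  2 × 3 RNA-seq libraries of 3×10⁵ fragments; fragment counts Poisson,
  isoform choice Bernoulli — the simplest laws matching the analysis'
  implicit assumptions.
* 10% planted fold-change genes (half ×4 up, half ×4 down); 25% planted
  AS genes cycling through all ten event types, with inclusion ratio 0.3
  in condition A and 0.7 in condition B (shift 0.4).
* 2 IP + 2 input RIP libraries of 10⁵ fragments; 15% of genes carry a
  100 bp IP-enriched peak (10-fold), all bearing the GC-rich 5-mer GCGCG
  written into the genome at the peak centre in transcribed orientation;
  5% of genes (disjoint) carry a shared IP/input artifact peak emulating
  expression pile-ups.
* reads are emitted pre-aligned (SAM, one single-end 50 bp record per
  fragment, `NH:i:1`, MAPQ 50): alignment is out of scope, so the
  simulator targets the pipeline's true input boundary. Read starts are
  uniform along the mature transcript (RNA-seq) or the gene span (RIP).

What it does **not** emulate — sequencing errors, PCR duplicates,
multimapping, paired-end bookkeeping, overdispersion between replicates,
non-uniform fragment start biases — bounds what green tests mean: they
show the algorithms are correct and calibrated under their own
assumptions, not that the statistical choices are optimal for real
libraries.

Everything is a deterministic function of the seed: the generator draws
genome and annotation under `seed`, RNA-seq libraries under `seed + 1`,
RIP libraries under `seed + 2`, in a fixed order, so rerunning any stage
reproduces byte-identical files.

## Numerical and convention choices

* Coordinates are 1-based closed throughout, the native convention of
  IRanges/GenomicRanges and of GTF and SAM; BED output converts on write.
* "Uniquely mapped" is operationalised as MAPQ ≥ 20 or an explicit
  `NH:i:1` tag, since uniqueness is never defined numerically by aligners
  in a portable way.
* Junction equality is exact (chromosome, strand, donor, acceptor).
* A read with k gaps supports k junctions (once per junction, not once per
  read).
* When one junction participates in several candidate events, all events
  are reported and shared counts are not deduplicated.
* Planted-event genes are written without CDS records; their exons are
  noncoding-exon features. This keeps two-isoform GTF semantics simple and
  costs nothing downstream because event detection never consults CDS.
* The IR alternative count is the mean over the two boundaries, mirroring
  the mean-over-junctions convention; boundary capture differs slightly
  from junction capture (an anchor of 5 bp versus 1 bp), which biases IR
  ratios by a few percent — irrelevant for the between-condition test,
  but worth knowing when interpreting absolute IR ratios.
* Ten of the events' names depend on strand (5' patterns on the minus
  strand appear at the genomic right); the generator and the grammar use
  the same strand-aware mapping, and tests cover both strands.

## Problem sizes used by the checks

The acceptance checks run five study-scale experiments (seeds 1–5 of the
default configuration above), one null experiment (no planted signal,
ratio shift 0, 10⁵-fragment RNA-seq libraries and 5×10⁴-fragment RIP
libraries) for calibration of the three significance tests, and an
exhaustively enumerable two-read case for the permutation null
(P(max height ≥ 2) = 2599/2601 for two 50 bp reads in a 100 bp gene).
These sizes were chosen so that planted effects sit well above their
binomial/Poisson noise floors while the full suite stays a desk-scale
computation.

## Known limitations

* The exact binomial DEG test assumes Poisson counts; see above.
* The event grammar anchors to annotated exon boundaries; fully novel
  exons are classified only insofar as their junction anchors coincide
  with annotated boundaries.
* At high coverage, peak intervals converge to gene spans (see the peak
  section); interpret peak widths accordingly.
* The k-mer stand-in ranks single k-mers; it does not build position
  weight matrices or merge shifted variants of one motif.
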