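---
title: "De novo bacterial transcriptome assembly: models and methods"
author: "denovotx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo bacterial transcriptome assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial RNA-seq experiments often concern organisms without a high-quality
reference genome — non-model isolates, mixed communities, unculturable
microbes. There the transcriptome must be assembled *de novo*, directly from
the reads. Bacterial data raise specific difficulties: dense genomes with
overlapping neighboring transcripts, polycistronic messages, expression
levels spanning several orders of magnitude, and datasets of tens of
millions of short reads that should ideally be processed on ordinary
hardware.

`denovotx` implements a two-stage assembly algorithm built around the
interplay of two data structures that are rarely combined: a **de Bruijn
graph**, the standard engine of de novo assembly, and a **Burrows-Wheeler
(FM) index**, the standard engine of reference-based alignment. The graph
proposes; the index disposes.

## Stage 1: candidate transcripts from a bounded de Bruijn graph

Each read is decomposed into its overlapping k-mers (`k = 25` by default;
k-mers containing `N` are skipped). The graph is a hash table whose keys are
k-mer *edges* and whose values are occurrence counts; the flanking
(k−1)-mer nodes are implicit. Before a k-mer is added, it is looked up in
the FM index of already-assembled candidates: k-mers that are already part
of a candidate transcript are not considered further, which keeps the graph
from re-accumulating mass on assembled sequence.

Candidate extraction is greedy path traversal. Any edge with count at least
`alpha` (default 50) seeds a path; the path extends while some edge
overlapping its terminal (k−1)-mer has count at least `beta` (default 5),
always taking the most frequent such edge. Traversed edges are removed, so
traversal terminates even on cyclic graphs. Each completed path is one
candidate transcript, immediately added to the FM index.

Two details the algorithm statement leaves open are fixed as follows:

* **Tie-breaking.** Among equal-count extension edges the lexicographically
  smallest base wins; among equal-count seeds the lexicographically
  smallest k-mer wins. This makes assembly fully deterministic.
* **Direction.** Extension goes rightward first, then leftward from the
  seed.

The graph never holds more than `capacity` edges (default 2^24). When an
insertion would exceed that, a reduction runs immediately and the
untraversed sub-`alpha` edges are discarded — low-frequency k-mers are
overwhelmingly sequencing errors, so this both bounds memory
deterministically and channels resources away from noise. The final,
end-of-input reduction keeps sub-`alpha` edges in place (they are simply
never seeded). A deterministic edge-capacity stands in for a raw memory
threshold so that runs are reproducible and testable.

**Strand policy.** For strand-ambiguous libraries (the default), every
k-mer is canonicalized to the lexicographic minimum of itself and its
reverse complement before any graph or index operation, and candidates are
reported in canonical orientation. For strand-specific libraries k-mers are
used as read, with mate 2 of a pair reverse-complemented first.

## Stage 2: full-length read-back filtering

Candidates are only k-mer-supported; stage 2 demands support by whole
reads. Every read is aligned full-length against the candidate index:
exact alignments by backward search (one rank step per read base), and
mismatch-tolerant alignments (`max_mismatches = 2` by default) by
pigeonhole seeding — the read is split into `max_mismatches + 1` equal
segments, at least one of which must match exactly; candidate loci are
verified by direct comparison. Alignments are ungapped; the error model of
the simulator is substitution-only for the same reason, a documented
limitation.

For paired-end data, both mates must align to the same candidate, on
opposite strands in inward orientation, with an implied fragment length
inside the configured insert bounds (defaults 1–500 nt); pairs violating
this scaffold consistency contribute nothing. A read aligning equally well
to several candidates is assigned to one uniformly at random; under a fixed
seed the assignment, and hence every downstream count, is reproducible.

Per-base alignment depth is accumulated along each candidate, and the
maximal regions with depth at least `epsilon` (default 20) at *every*
position are retained — we read "at least epsilon reads align throughout
the region" as per-base depth rather than read-start density, the most
direct interpretation. Regions shorter than `min_transcript_length`
(default `2k` = 50 nt, the shortest length with non-trivial k-mer support)
are dropped. Final per-sample counts are recomputed over the retained
intervals: a read counts toward a transcript when its alignment lies within
the interval.

Because reads are positioned uniformly, coverage ramps up over the first
read-length of every transcript, so the retained region trims roughly
`epsilon * read_length / coverage` nt from each end. This end-trimming is
why sensitivity on synthetic data saturates near, but not at, 1.

## The FM index

The index stores the Burrows-Wheeler transform of the concatenated
candidates, one sentinel per sequence (sentinels sort before the alphabet,
among themselves by document order). The suffix array is built by prefix
doubling (O(N log² N), entirely adequate at the candidate sizes involved);
rank is checkpointed every 128 symbols and suffix-array positions are
sampled every 32 suffixes, recovered by LF-walking, so counting a pattern
of length m takes exactly m constant-work steps. Patterns never span a
sentinel. Incremental addition is a batched rebuild amortized over
reduction rounds; behavioral equivalence with a fresh build is the
contract, and is tested.

## Post-assembly analyses

**Normalization.** Each sample's factor is its nearest-rank upper quartile
(the ceiling(0.75 n)-th order statistic) of *non-zero* transcript counts,
divided by the geometric mean of the upper quartiles across samples.
Nearest-rank avoids interpolation ambiguity, and the quartile is computed
on non-zero counts following the normalization literature this scheme comes
from. Dividing by the factors equalizes upper quartiles exactly.

**Abundance.** Reads per transcript divided by transcript length in kb and
the sample's factor — RPKM-like, but with the fragile per-million
normalizer replaced by the robust upper-quartile one. The `scale` constant
defaults to 1, i.e. units of reads per kilobase per upper-quartile.

**Mean-variance smoothing.** Within each condition with replicates (all
samples pooled blind when none has them), per-transcript means and
variances of normalized counts are computed. Raw sample variances are
unbiased but, at bacterial replicate numbers (often 2), extremely noisy,
and two tempting estimators fail: log-transforming them point-wise before a
log-scale fit biases the curve downward by E[log s²] − log σ² (≈ −1.27 at
two replicates), while fitting raw variances against log mean suffers
convexity bias, since power laws are convex in log abscissa. The estimator
used here averages raw variances within ~n/40 narrow quantile bins of log
mean — narrow enough that within-bin curvature is negligible — and then
puts a tricube-weighted local *linear* fit (bandwidth 0.3 of the span of
log means, evaluated on a 50-point grid, interpolated between grid points)
through the binned points in log-log coordinates, where power-law
mean-variance relationships are linear. Predictions are clamped below at
the Poisson line (variance ≥ mean). With fewer than two usable points the
model degrades to pure Poisson with a warning.

**Differential expression.** For two conditions, the summed size-adjusted
counts K_A and K_B are each modeled as negative binomial with mean equal to
the pooled normalized mean scaled by the condition's summed size factors
and variance from the smoothed model (Poisson limit when the fitted
variance does not exceed the mean). The p-value is the conditional
probability, given the total K = K_A + K_B, of any split (a, b) no more
likely than the observed one:

$$ p \;=\; \frac{\sum_{a+b=K,\;P(a)P(b)\le P(K_A)P(K_B)} P(a)P(b)}
              {\sum_{a+b=K} P(a)P(b)} $$

The sum is evaluated in full (vectorized over all K+1 splits; at the count
totals bacterial transcripts reach this is microseconds, so no term
truncation is applied). Identical observations give p = 1 exactly.
Benjamini-Hochberg q-values are reported for FDR control.

## Evaluation framework

Assemblies are scored against an annotated genome with five metrics. Since
not every annotated gene is expressed, metrics that reference the
annotation use only **reference genes**: genes whose every k-mer occurs in
at least one read — the evaluable subset.

* **Specificity** — fraction of transcripts aligning to the genome over at
  least δ = 1.0 of their length (one minus the false-positive rate).
* **Sensitivity** — fraction of reference-gene bases covered by aligned
  transcripts; a genome-wide variant (|G covered|/|G|) serves DNA-seq
  assemblies.
* **Contiguity** — fraction of reference genes ≥ δ = 0.8 covered by their
  single best transcript.
* **RMBT** — fraction of reads aligning full-length back to the assembled
  transcripts.
* **Accuracy** — among aligning transcripts, the fraction of alignment
  columns that are perfect matches.

Two evaluation aligners back these metrics. For the δ = 1.0 metrics, exact
substring matching against both genome strands is sufficient and
unambiguous. The permissive aligner — used for accuracy and for the
expression-decile analysis — rescues near-exact transcripts by
seed-anchored local alignment: exact 25-mer seeds at stride 20 locate the
best diagonal, and a unit-cost local alignment over a ±100 nt window is
accepted at ≥ 95% identity over ≥ 50 columns. An E-value cut-off would
have been database-size dependent, so a fixed identity/length criterion is
used instead.

The decile analysis sorts reference genes by expression, splits them into
10 equal groups (remainder to the highest deciles, ties broken by gene id)
and computes sensitivity and contiguity per group. Because a single
synthetic dataset puts only a handful of reference genes in each decile,
the acceptance check averages the decile curves of several replicate
simulations — the same way the published form of this analysis averages
over datasets — before asserting that sensitivity rises weakly with
expression through decile 8.

## The synthetic data generator

`simulate_dataset()` emulates the structure of a bacterial RNA-seq
experiment at desk scale: an i.i.d. uniform genome (200 kb by default), 50
non-overlapping transcripts of 500–2,000 nt on random strands,
per-transcript coverage drawn log-uniformly (50–200× by default, mirroring
the orders-of-magnitude expression spread of real transcriptomes), and
100-nt reads placed uniformly with independent per-base substitution
errors; paired mode draws inward-oriented fragments from a truncated
normal. Every stage is deterministic given the seed (sub-stages derive
seeds seed+1, seed+2 so they are reproducible standalone as well).

What it deliberately does **not** model: positional coverage bias, indels,
quality-score-dependent errors, rRNA contamination, and overlapping
transcripts/operon structure (an overlap-free layout is what makes exact
recovery checkable; overlapping transcription is precisely the hard case
for which no recovery target is set). Passing tests on this generator
therefore demonstrate algorithmic correctness — exact recovery of
well-separated, well-covered transcripts, calibrated statistics — not
performance on real libraries.

## Problem sizes and numerical choices

The validation harness runs at sizes chosen to exercise every code path
while keeping the full suite fast on a single CPU: end-to-end checks use
50 transcripts in 200 kb at 100× (~60,000 reads); the decile analysis
averages six replicates of 100 transcripts in 400 kb; the null calibration
of the NB test uses 2,000 transcripts at 2 vs 2 replicates; FM-index
oracles use twenty 5-kb texts with 1,000 random patterns each. Tie-breaks,
clamps and degenerate-input behavior (empty read sets, all-zero samples,
constant counts, genes shorter than k) are fixed as described above and
asserted in the test suite.

## Known limitations

Ungapped alignment only (an indel in a read makes it unalignable in stage
2); no bubble popping or tip clipping beyond the α/β frequency thresholds;
no scaffolding of candidates using mate pairs (pairs act only as an
alignment filter); two-condition differential expression only; k ≤ 31
(k-mers are packed two bits per base into one machine word).
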