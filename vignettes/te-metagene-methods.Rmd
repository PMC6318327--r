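---
title: "Metagene analysis of transposable-element chromatin: models and methods"
author: "TEmetagene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metagene analysis of transposable-element chromatin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transposable elements (TEs) make up the larger part of mammalian genomes
and are kept in check by the chromatin system: heterochromatic marks such
as H3K9me3 and DNA 5mC silence them, while many TE types additionally
carry activatory or even bivalent mark combinations. Measuring chromatin
at TEs is complicated by multimapping: a short read rarely identifies an
individual TE copy. TEmetagene follows the metagene convention for this
situation — each TE *type* (a RepeatMasker repName such as `L1Md_Gf`, with
all of its genomic copies) is treated as a single aggregate feature, and
every statistic is computed at the type level.

The package implements the full analysis chain: catalog ingestion and
filtering, the max-bin enrichment statistic with a size-matched random
background, enrichment calls and High/Low partitions, the bipartite
mark–TE network, TE age from Jukes–Cantor-corrected divergence,
differential expression of genes and TE types after chromatin-modifier
knockdown, the 20% chromatin-accessibility rule with Fisher testing, and
2C-like signature scoring. A synthetic-data module generates
coordinate-level fixtures with planted, known effects so that every stage
is testable without any external download.

## The enrichment statistic

For a coverage track (RPKM-normalised ChIP/ATAC signal) and a TE type:

1. Every copy is cut into consecutive 500-bp bins anchored at its 5' end
   (strand-aware; the final partial bin keeps its per-base mean; copies
   shorter than one bin contribute a single bin).
2. The metagene profile is the per-bin-index mean over all copies that
   reach that bin; the **observed** value is the profile's maximum bin.
3. The **expected** value is the same statistic computed on one random
   region per copy, with exactly the copy's length, drawn uniformly over
   the genome (chromosomes weighted by length).
4. The cell value is `log2((obs + pc) / (exp + pc))` with a pseudocount
   `pc = 0.01` RPKM that bounds folds when the background is empty.

Two details were genuinely open and are fixed as follows. First, binning
could be read per copy (max per copy, then aggregate) or per metagene
(aggregate per bin, then max); the metagene reading is used, because the
type-as-metagene convention governs the whole analysis and the per-copy
max is noisier; the alternative would be a one-line change and is
deliberately not exposed until someone needs it. Second, the background
is drawn once per (type, seed) and shared by all marks of a run, so that
mark-to-mark comparisons face the same null; the seed is recorded in the
result object.

On the toy genomes the package generates (1–5 Mb), TEs occupy several
percent of the sequence, so an unconstrained random background would
regularly re-sample the TE signal itself and inflate the expected value
(about +0.4 log2 on the standard fixture). The default background
therefore excludes the catalog's own copies by rejection sampling; at
genome scale, where a single type occupies a negligible fraction, the two
backgrounds coincide. `exclude = NULL` restores the fully unconstrained
background, and a custom exclusion set (assembly gaps, blacklists) can be
supplied.

Calls are strict: a mark is enriched at a TE type when its linear fold is
`> 2` (a fold of exactly 2 is not a call); the relaxed exploratory
threshold is `> 1.5`. The network module draws an edge for every passing
(mark or modifier, TE type) cell; because one figure convention reads "at
least 2-fold", the comparator is configurable there, with strict `>` as
the default for consistency.

## Catalog rules

Copies shorter than 300 bp are removed first; then TE types with fewer
than 50 remaining copies are removed entirely. The order matters (the
length filter can push a type below the copy threshold) and is fixed
length-first, matching the order in which the rules are stated. LINE
types can be split into `__long` (> 5 kb, strict) and `__short`
pseudo-types; a copy of exactly 5 kb is short.

TE age uses the type's mean milliDiv (unweighted across copies; a
length-weighted variant is a flag): `p = milliDiv / 1000` is the
proportion of substituted sites against the family consensus,
`d = -(3/4) ln(1 - 4p/3)` the Jukes–Cantor distance, and `T = d / r` the
age at `r = 4.5e-9` substitutions per base per year. Because divergence is
measured against the consensus — an estimate of the ancestral state — the
single-lineage convention (no factor of 2) is the default; both
conventions are in published use for repeats, so `doubled = TRUE` exposes
`T = d / 2r`. Types with `p >= 0.75` are outside the model's domain and
are flagged with `NA` age rather than dropped. At small `p` the estimate
approaches `p / r`, which the tests verify to 0.1% at `p = 1e-4`.

## Differential expression

The DE engine is a deliberately simple, documented stand-in: a
per-feature negative-binomial model with method-of-moments dispersion
shrunk toward the trimmed-mean common dispersion, and a Wald test
(standard normal reference) on the log fold-change, Benjamini–Hochberg
corrected jointly over genes and TE metafeatures. Calls require adjusted
`P < 0.05` and linear fold strictly above 2 (or below 1/2). The engine is
not a reimplementation of a full DE framework; it exists so the
thresholds and TE summaries around it are testable end-to-end, and the
test suite cross-checks its calls against an established NB engine on a
planted fixture.

Two normalizations serve different purposes. Quantification uses joint
full-quantile normalization over genes and TEs together (every sample's
sorted distribution becomes the cross-sample mean distribution; an
optional loess GC adjustment can precede it and is off by default, since
it is unclear whether GC correction should apply to TE metafeatures at
all). Testing, however, uses median-of-ratios size factors on the raw
counts: quantile normalization assumes mostly-unchanged, symmetric
distributions, and under a strong asymmetric knockdown it compresses a
genuine 4-fold to about 2.6-fold, which the `|fold| > 2` filter then
punishes — measured on the standard fixture, sensitivity drops from 0.98
to about 0.78. Size factors are robust to that asymmetry and are what NB
DE frameworks themselves apply. A caller who wants the quantile-normalised
matrix tested anyway can pass `normalization = "normalized_assay"`.

With a single replicate per group the dispersion is pooled across all
features and a warning is emitted; all-zero features are excluded and
flagged, never silently dropped.

## Accessibility and signatures

TE accessibility is the length-weighted mean per-base RPKM over a type's
copies — an aggregate openness measure, not the max-bin peak statistic,
because the question is overall chromatin opening rather than focal
enrichment (the max-bin variant would be easy to add behind the same
surface if peak-style accessibility is wanted). The 20% rule calls a type
`opened` at fold `>= 1.2` against control and `closed` at `<= 0.8`,
boundaries inclusive, after a small pseudocount. Association between
opening and a chromatin mark is a two-sided Fisher exact test
(point-probability method) on the opened-by-enriched 2×2 table at
`P < 0.01`; peak-to-gene linkage uses a 10-kb gap window, inclusive, with
overlap as distance zero.

The 2C-like analysis builds a signature as the top-200 genes by
fold-change (pseudocount 1) of a 2C-vs-ESC reference table, ties broken
by gene id; knockdowns are scored by the median and mean log2 fold of the
signature genes against control, with a one-sided Mann–Whitney test
versus non-signature genes — both location summaries are reported because
either could be the figure convention. The reverse direction takes the
top-200 upregulated genes of a knockdown and asks in which reference
stage they are high. MERVL-proximal genes are annotated within 10 kb of a
`MERVL-int` or `MT2_Mm` copy; "flanking" includes overlap, and when both
same- and opposite-strand copies qualify the gene is labelled `same_ori`,
since the biological signature of interest — same-strand splicing of
MERVL into the gene — only needs one same-strand element.

## The synthetic-data model, and what it does not emulate

The generator is coordinate-only: a toy genome of a few megabases with
2–4 chromosomes, TE types placed by rejection sampling without overlap,
lengths uniform within a per-type range (0.3–7 kb overall), copy numbers
in the tens-to-hundreds, milliDiv per copy `Normal(mean, 30)` clipped to
[0, 1000]. Coverage tracks are background 1.0 plus Gaussian noise
truncated at zero (default `noise_sd = 0.25`, a visually realistic
roughness for RPKM tracks), with planted effects multiplying the signal
over a type's copies — uniformly or only over the 5'-most 500 bp, the
pattern long LINEs show in real chromatin data. A background level of
exactly 1.0 makes the planted magnitude equal the expected fold, so
oracle arithmetic in the tests is trivial. Count matrices are negative
binomial with planted group-mean folds (dispersion 0 degrades to
Poisson); the demo plants strong 6–8× deregulation at dispersion 0.05,
the regime of robust knockdown responses, while the recovery benchmarks
use the harder 4× / dispersion 0.1 setting. The 2C table plants exactly
`n_top` top-fold genes. Toy genes are anchored near MERVL-like copies in
both orientations to exercise the proximity annotation.

What passing tests on these fixtures show is that the statistics,
thresholds and bookkeeping are implemented correctly and recover known
truth under realistic noise. What they cannot show: mappability
structure, copy-to-copy sequence divergence, GC and insert-size biases,
peak-shaped ATAC signal, library-size variation, or the correlated
biology of real chromatin — the fixtures have none of these. Numbers
from real data will be noisier in ways the toy model does not represent.

## Problem sizes and numerical choices

The test suite and the acceptance script run fixtures of ~1–3 Mb with
3–5 types × 55–120 copies, 5–50 seeds per property, and a full demo run
(annotation → enrichment → network → expression → ATAC → signatures) on a
3-Mb genome; these sizes give stable recovery statistics while keeping a
complete run in minutes on one CPU. All randomness flows through
explicit seeds; repeated runs are byte-identical for text outputs.
Degenerate inputs are defined, not accidental: zero-signal cells are fold
1 by pseudocount and flagged; constant vectors have correlation distance
1 and undefined Spearman rho with a warning; empty Fisher margins give
`NA`; an all-discordant replicate set keeps the highest-coverage track
with a warning.

## Limitations

The package does not align reads, call peaks, discover motifs, or
redistribute multimappers by EM — alignments and peaks are inputs, and
the multimapper convention is the upstream aligner's random-best
placement. The DE stand-in has no per-feature dispersion trend, no
outlier handling and no fold shrinkage. Genome-scale results additionally
depend on the quality of the RepeatMasker annotation and on the
RPKM-normalisation of the input tracks, both taken at face value.
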