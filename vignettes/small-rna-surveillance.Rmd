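---
title: "Detecting small RNA biogenesis signatures: methods and design notes"
author: "sRNAsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small RNA biogenesis signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAsurv)
```

## The problem

Small RNA populations carry the fingerprints of the machinery that made
them. Two mechanisms leave geometrically distinct marks in genome
alignments:

* **Dicer (RNase III) processing** of double-stranded precursors produces
  sibling reads on opposite strands whose duplex carries 2-nt 3′
  overhangs. For a size-matched pair of length $L$, the distance between
  the two 5′ ends (counting both end positions) is exactly $L - 2$.
* **Ping-pong amplification** by Piwi-clade slicers cuts a target 10 nt
  from the 5′ end of the bound guide, so sense/antisense read pairs
  overlap by exactly 10 nt at their 5′ ends, classically with a U at guide
  position 1 whose partner is an A at responder position 10.

Given a small RNA library aligned to a genome, `sRNAsurv` asks which
register dominates — globally, per read-size class, and per locus — and
supports the surrounding bookkeeping of such a study: genome segmentation
into feature classes, read-set cleaning, discovery of highly expressed
loci, identification of dual-strand TE-fragment "master" loci, per-context
cytosine methylation accounting, and assembly decontamination statistics.
A mechanism-labelled synthetic data generator provides ground truth for
validating every statistic.

## The overlap signature statistic

Alignments are reduced to 5′-end count profiles $c^+_{L}(p)$ and
$c^-_{L}(p)$ per chromosome, strand and read length, where the 5′ end of a
minus-strand read is its rightmost base and counts are weighted by
collapsed copy number. For an overlap $o \in [1, 30]$ the pair count is

$$Z(o) = \sum_{\mathrm{chrom}} \sum_p c^+_{L_1}(p)\; c^-_{L_2}(p + o - 1),$$

i.e. the number of (plus, minus) read pairs whose 5′ ends are in register
$o$. The reported score is the z-standardization over the window,
$z(o) = (Z(o) - \mu)/\sigma$ with the population SD; a zero-variance
window (no overlapping pairs at all) is flagged undefined and rendered
blank rather than zero. Pairs are counted by 5′ distance alone — the
statistic does not require both reads to span the overlap physically;
requiring physical overlap is available as an option but off by default.

Design notes on this statistic:

* The pair-count (product) form is used; because the score is
  z-standardized it is invariant to any global normalization, which is
  why we document this form as canonical here.
* The window is $o \in [1, 30]$, matching the 18–30-nt read range.
* Population (not sample) SD: the window is a fixed descriptive support,
  not a sample from a larger one.
* Argmax ties break toward the smallest overlap, deterministically.
* The "all" column pools the 5′-end profiles over all sizes before
  counting, so each $(L_1, L_2)$ combination contributes exactly once —
  the alternative of averaging per-size z-scores is noted but not used.

For size-matched pairs the **overhang signature** is the same curve read
on the axis $h = L - o$: a Dicer population peaks at $h = 2$. The
`averaged_overhang()` summary computes the z-curve for each size pair
18/18 … 28/28 on uniquely mapping reads, transposes each to overhang
space, and averages across sizes at each $h$ — this is the single most
robust Dicer-register readout and the quantity the acceptance script
reports.

## Mapping, capping, segmentation

`map_reads_exact()` reports *every* exact occurrence of every read
(forward and reverse-complement) so that repetitive targets are fully
represented; `cap_multimappers()` then removes all events of reads with
at least 100 mapping events (reads mapping *fewer than* 100 times are
kept — the boundary read with exactly 100 events is discarded). Feature
assignment uses any-overlap (≥ 1 bp) with precedence
rRNA > tRNA > snRNA > miRNA > mRNA > TE > master > unknown, chosen because
abundant structural ncRNAs dominate contamination and should win when
annotations collide; ties within a class go to the leftmost locus.
`clean_by_feature()` keeps only reads none of whose mapping events touch a
non-target class. `discover_expressed_loci()` merges the footprints of
alignments outside the annotation (gaps ≤ 50 bp bridged by default) and
applies *strict* thresholds: copies-weighted read count > 1000 and span
> 200 bp. "Read density" is interpreted as a copies-weighted count per
locus; a per-kb rate is the documented alternative. Multimapped events
each count with the read's full copy weight; 1/n-hits weighting is an
option, off by default.

Internally every range is a `GRanges` (1-based, closed); BED and the
methylation TSV are 0-based on disk and converted only at the I/O
boundary.

## Master loci

A master locus is called from the expressed-locus candidates when it is
(a) dual-strand — strand bias ≤ 0.3, a default chosen to operationalize
"similar read rates on both strands" in the absence of a stated number —
and (b) carries at least one exact TE-homologous segment. Homology is
operationalized exactly: maximal exact matches ≥ 25 bp between locus and
TE catalog (either orientation) for segments, and exact full-length
membership (either orientation) for the read-accountability fraction.
Exactness keeps the tests deterministic and database-independent; a
mismatch-tolerant mode is deliberately out of scope, so accountability
figures here are a conservative proxy for BLAST-style homology fractions.

## Methylation accounting

Per-cytosine calls (Bismark-style columns) are filtered to coverage
strictly greater than 4 reads — the wording "more than 4 reads" is taken
literally, so coverage 5 is the minimum retained. Rates are pooled, not
per-site-averaged: $100 \cdot \sum m / \sum (m+u)$ per context × feature
class, which weights sites by coverage. Contexts follow the standard
trinucleotide rules (CG, CHG, CHH with H ∈ {A, C, T}; minus-strand
cytosines evaluated on the reverse complement; chromosome-end cytosines
with truncated trinucleotides fall into CHH). Denominators report covered
cytosines; total call rows are emitted alongside so either convention can
be read off.

## Assembly decontamination

A contig's matched fraction is the length of the *union* of its
foreign-hit intervals divided by contig length — union rather than summed
HSP lengths, so the fraction cannot exceed 1; the summed mode is a switch.
Contigs are discarded when the fraction strictly exceeds 10% (exactly 10%
is kept). N50 is the largest length $L$ such that contigs ≥ $L$ bp sum to
at least half of the assembly. Hit tables are consumed (BLAST
outfmt-6-like TSV); no homology search is executed.

## The synthetic data generator

`simulate_srna_dataset()` plants, under one global seed and in a fixed
draw order: a single-contig genome hosting dispersed copies of each TE
family, a dual-strand master locus concatenated from exact ≥ 25-bp TE
fragments in mixed orientations, mRNA and structural ncRNA loci; then
Dicer duplexes (both arms share one length; minus arm offset −2),
ping-pong pairs (guide and responder lengths drawn independently; 5′
overlap exactly 10), single-stranded degradation fragments (uniform start,
truncated at the transcript 3′ end, with fragments shorter than 18 nt
resampled to mirror library size selection), and per-cytosine methylation
calls (Poisson depth, binomial methylated counts at the context rate).

Defaults are the study conditions this package models: mixture
dicer = 0.75 / pingpong = 0 / degradation = 0.25, a unimodal size
distribution peaked at 24 nt, no 5′-U bias (0.25, i.e. uniform), 0.5%
methylation in every context, and 6× mean coverage. Tests that need a
ping-pong population or a strong 1U bias set those parameters explicitly
as experimental conditions.

Two generator decisions deserve emphasis:

* **The 1U/10A coupling.** With a 10-nt 5′ overlap, responder position 10
  sits on the complement of the guide's first base, so "probability of U
  at guide position 1" and "probability of A at responder position 10"
  constrain the *same* genomic base. One Bernoulli per pair decides it:
  the base is T on the guide sense with probability
  $1 - (1-b_{1U})(1-b_{10A})$, otherwise uniform over {A, C, G} — so the
  planted 5′-U frequency equals `guide_5p_bias` exactly when the responder
  bias is zero, and the two biases combine as independent events
  otherwise. The edit happens on the genome before read extraction, so
  reads always equal their genomic subsequence.
* **Collision-free planting.** Guide 5′ positions are drawn without
  replacement within the locus so no planted base is overwritten by a
  later pair; with replacement, opposite-strand collisions measurably
  dilute the planted bias.

What the generator does *not* emulate: sequencing error, adapter
contamination, Zucchini-style phased biogenesis, miRNA hairpins, or
length-dependent ligation biases. Passing recovery tests therefore shows
the statistics are correct on clean mechanistic signal, not that they are
robust to every artifact of real libraries.

## Numerical choices and degenerate inputs

* Zero-variance signature windows are undefined (blank), never zero.
* Argmax ties break toward the smallest overlap/overhang.
* Coverage metagenes use 100 bins (mean within bin; loci shorter than the
  bin count are linearly interpolated) oriented 5′→3′ along the locus
  strand; the 3′-enrichment score mean(last decile)/mean(first decile)
  is capped at a sentinel of 1000 when the first decile is empty.
* Empty read sets: `strand_bias` and the size-distribution mode are NA;
  `averaged_overhang` and `te_read_accountability` raise errors, since a
  silent value would be misleading.
* Information content is $2 + \sum_b f_b \log_2 f_b$ bits with no
  small-sample correction (descriptive use at large n).

## Problem sizes

The validation suite and the acceptance script run on toy genomes of
40–80 kb with 1000–3000 simulated duplexes or pairs per scenario — sizes
chosen so every recovery check has comfortable statistical power (planted
register counts far above the chance-coincidence background, which grows
with read density) while an entire run stays interactive on a laptop.
Size-matched ping-pong checks use 3000 pairs because independent guide
and responder lengths leave only ~n/169 truly size-matched pairs per
class.

## Known limitations

* Exact matching only: no mismatch tolerance anywhere (alignment,
  homology segments, read accountability). This is a documented
  operationalization, not an approximation of a specific aligner.
* Master-locus homology fractions are conservative relative to
  similarity-search-based figures.
* The overlap statistic assumes 5′ ends are informative; libraries with
  degraded 5′ ends will blur every register.
* Whether per-position normalization should precede z-scoring is an open
  question in the literature's usage; the scale-invariant z of raw pair
  counts is used here.
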