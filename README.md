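# sRNAsurv

Small RNA biogenesis signatures and genome surveillance analysis in R.

Small RNA populations record how they were made. Dicer (RNase III)
processing of double-stranded RNA leaves sibling reads on opposite strands
in a register 2 nt shorter than the read length — the 2-nt 3′ overhang
signature of siRNA duplexes. Ping-pong amplification by Piwi-clade slicers
leaves sense/antisense pairs whose 5′ ends overlap by exactly 10 nt, the
classic piRNA mark. `sRNAsurv` detects and quantifies these registers in
genome alignments of 18–30-nt reads, and implements the surrounding
analysis a genome-surveillance study needs: exact read mapping with a
multimap cap, genome segmentation into feature classes, per-class read
cleaning, expressed-locus discovery, per-locus strand bias / size
distributions / 5′ composition / coverage metagenes, discovery of
dual-strand TE-fragment **master loci** that catalog restricted sequences,
per-context (CG/CHG/CHH) bisulfite methylation rates with a coverage
filter, and assembly decontamination statistics (matched-fraction filter,
N50). A mechanism-labelled synthetic data generator provides ground truth
for every statistic.

## The core statistic

Alignments are reduced to copies-weighted 5′-end count profiles
`c⁺_L(p)` / `c⁻_L(p)` (the 5′ end of a minus-strand read is its rightmost
base). For overlap `o` in 1..30,

    Z(o) = Σ_chrom Σ_p  c⁺_L1(p) · c⁻_L2(p + o − 1)

counts the plus/minus read pairs whose 5′ ends sit in register `o`; the
reported score is the z-standardization of `Z` over the window (population
SD; zero-variance windows are "blank"). A Dicer population of size-matched
reads of length `L` peaks at `o = L − 2`, equivalently at overhang
`h = L − o = 2`; a ping-pong population peaks at `o = 10` for all sizes.

## Worked example

```r
library(sRNAsurv)

cfg <- sim_config(seed = 1, n_reads = 4000)   # dust-mite-like defaults:
sim <- simulate_srna_dataset(cfg)             # 75% Dicer, 25% degradation

aln <- map_reads_exact(collapse_reads(sim$reads), sim$genome)$alignments
aln <- cap_multimappers(aln)$kept             # drop reads with >= 100 hits

m <- signature_matrix(aln)                    # overlap z-scores, per size
attr(m, "argmax")
#>  18  19  20  21  22  23  24  25  26  27  28  29  30 all
#>  NA  NA  18  19  20  21  22  23  24  25  26  27  NA  23

size_distribution(aln)$mode
#> [1] 24

attr(averaged_overhang(aln), "argmax")
#> [1] 2

strand_bias(aln, sim$annotation[sim$annotation$feature_class == "master"])
#> [1] 0.001

rates <- context_rates(filter_coverage(sim$methyl_calls, 4), sim$annotation)
rates[rates$feature_class == "genome", c("context", "rate_percent", "n_sites")]
#>  context rate_percent n_sites
#>       CG    0.4559295    8802
#>      CHG    0.5302630    6668
#>      CHH    0.5002970   20163
#>      all    0.4949068   35633
```

Read it as: every populated size class peaks at overlap `L − 2` (column
`20` peaks at 18, column `24` at 22, …) — the Dicer register; the averaged
size-matched overhang curve peaks at 2 nt; the modal read size is the
planted 24 nt; the master locus is read from both strands almost equally
(bias ≈ 0); and the recovered genome-wide methylation rate is ≈ 0.5% in
every context, as planted. Blank (`NA`) columns are size classes with no
overlapping pairs.

The full chain — simulate → map → cap → segment → clean → signatures →
locus metrics → master loci → methylation → assembly stats — runs as
`run_pipeline(cfg, "outdir")`, or from a shell via
`inst/scripts/run-pipeline.R`.

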