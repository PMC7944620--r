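# triadtrack

Quantify, classify and track subgenome bias of histone modifications and
gene expression across homoeolog triads in polyploid wheat.

## The problem

Bread wheat and its tetraploid relatives carry several homoeologous copies
of most genes — one per subgenome (A, B, D) — organised as 1:1:1 **triads**.
Whether the two ancestral tetraploid subgenomes (A and B) carry a histone
mark (H3K4me3, H3K27me3) or express a gene evenly, and whether that balance
is stable through domestication and through ploidy transitions, is a core
question for allopolyploid genome evolution. `triadtrack` implements the
full gene-level analysis for users with per-gene read-count tables from
homoeolog-specific ChIP-seq or RNA-seq: epigenomicists and wheat
geneticists who want the triad-level statistics without re-deriving the
plumbing.

## The method

For each sample, gene counts are converted to TPM
(`TPM_g = 10^6 (c_g/L_g) / Σ_h (c_h/L_h)`, with `L` in kb). A triad is
**modified** by a mark (or expressed) when its A or B homoeolog exceeds
0.5 TPM. Each modified triad is normalized within itself,
`rel_A = TPM_A / (TPM_A + TPM_B)`, and assigned to the category whose
anchor is nearest in Euclidean distance in the `(rel_A, rel_B)` plane:

| category | anchor |
|---|---|
| A = B (balanced) | (0.5, 0.5) |
| A > B            | (1, 0)     |
| A < B            | (0, 1)     |

which places the balanced/biased boundary exactly at `rel_A` = 0.25 and
0.75. Categories are then tracked across three-genotype series — the
domestication series WTW → DTW → ETW (Group I–IV) and the ploidy-transition
series TAA10 → ETW → XX329 (Pattern I–IV) — where the label encodes which
of the three genotypes changed state. Supporting statistics are an exact
binomial test of A-vs-B asymmetry among biased triads, two-sample
proportion tests, Wilcoxon rank-sum comparisons of modification level,
hypergeometric GO enrichment with Benjamini–Hochberg FDR, chromosomal zone
(distal / interstitial / proximal) distributions, and a
modification-expression concordance table. A synthetic-data generator with
planted ground truth (negative-binomial replicate noise, exact planted
category and label frequencies) backs the end-to-end validation.

## Worked example

Simulate a domestication series with 2000 triads for H3K4me3, then run the
pipeline:

```r
library(triadtrack)
cfg <- sim_config(n_triads = 2000, assays = "H3K4me3", seed = 42)
sim <- simulate_series(cfg, label_freqs = c(0.883, 0.048, 0.033, 0.036),
                       series = "domestication")
sm <- signal_matrix_from_sim(sim)
calls <- classify_dataset(sm, sim$triads)
summary(calls)
#>   genotype   assay n_triads n_modified pct_modified n_eq n_gt n_lt   pct_eq    pct_gt   pct_lt pct_biased
#> 1      DTW H3K4me3     2000       1631        81.55 1348  164  119 82.64868 10.055181 7.296137   17.35132
#> 2      ETW H3K4me3     2000       1634        81.70 1331  161  142 81.45655  9.853121 8.690330   18.54345
#> 3      WTW H3K4me3     2000       1630        81.50 1464   95   71 89.81595  5.828221 4.355828   10.18405
```

About 81% of triads pass the 0.5 TPM filter in each genotype, most of them
balanced. Tracking the categories across the series recovers the planted
transition structure:

```r
tracks <- track_series(calls, "domestication")
tabulate_tracks(tracks)
#>     assay label    n proportion n_tracked n_not_tracked
#> 1 H3K4me3     I 1411 0.87098765      1620           380
#> 2 H3K4me3    II   84 0.05185185      1620           380
#> 3 H3K4me3   III   60 0.03703704      1620           380
#> 4 H3K4me3    IV   65 0.04012346      1620           380
```

87.1% of tracked triads keep the same A/B state across all three genotypes
(planted: 88.3%, slightly eroded by replicate noise). The asymmetry test
asks whether biased triads favour the A subgenome:

```r
asymmetry_tests(calls)
#>   genotype   assay n_gt n_lt     p_value
#> 1      DTW H3K4me3  164  119 0.008791302
#> 2      ETW H3K4me3  161  142 0.301093389
#> 3      WTW H3K4me3   95   71 0.073919093
```

and replicate QC confirms the noise model (`replicate_correlation(sm)`
gives Pearson r ≈ 0.99 for this mark).

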