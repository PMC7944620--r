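---
title: "Methods: triad bias classification and cross-genotype tracking"
author: "triadtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triad bias classification and cross-genotype tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadtrack)
```

## The model

`triadtrack` analyses homoeolog triads — 1:1:1 sets of A/B/D subgenome
gene copies in polyploid wheat — for bias in histone-mark or expression
signal between the A and B subgenomes, and for the stability of that bias
across genotype series.

**Quantification.** Gene-level read counts (from homoeolog-specific
mapping, counted per gene body) are converted to TPM over the full gene
universe of each sample, so each column sums to $10^6$. TPM is the only
normalization used: the within-triad analysis below is invariant to any
further per-sample scaling, and between-sample methods (TMM, quantile)
would interfere with the absolute 0.5 TPM filter. Replicates are combined
by the per-gene arithmetic mean of TPM before classification (how the
original two replicates per line were combined is not derivable from the
data descriptions we emulate; the mean is the least-informative choice and
`aggregate_replicates(method = "separate")` exposes the alternative).

**Modification filter.** A triad is modified (for ChIP marks) or expressed
(RNA) when its A *or* B homoeolog strictly exceeds $\tau = 0.5$ TPM.
Triads failing the filter carry no category: they are excluded from
category tabulations and from tracking denominators, because a state
comparison requires a state at every genotype.

**Classification.** A modified triad is summarised by
$\mathrm{rel}_A = \mathrm{TPM}_A / (\mathrm{TPM}_A + \mathrm{TPM}_B)$ and
assigned to the nearest of three anchors in the
$(\mathrm{rel}_A, \mathrm{rel}_B)$ plane — $(0.5, 0.5)$ balanced,
$(1, 0)$ A-dominant, $(0, 1)$ B-dominant — by Euclidean distance. On the
simplex this reduces to thresholds at $\mathrm{rel}_A = 0.25$ and $0.75$;
the package computes and reports all three distances anyway, as they are
the method's definition and useful diagnostics. For hexaploid genotypes the
D homoeolog is ignored: $\mathrm{rel}_A$ is always computed over A + B
only, so tetraploid and hexaploid lines are compared on the same scale.

**Tracking.** Across a three-genotype series the per-triad category
sequence $(c_1, c_2, c_3)$ is reduced to a label determined only by the
equalities among the three:

* domestication series (WTW → DTW → ETW): Group I $c_1=c_2=c_3$;
  II $c_1\neq c_2=c_3$; III $c_1\neq c_2,\ c_2\neq c_3$;
  IV $c_1=c_2\neq c_3$.
* ploidy series (TAA10 → ETW → XX329): Pattern I $c_1=c_2=c_3$;
  II $c_1\neq c_2,\ c_1=c_3$ (reversible, extraction-dependent);
  III $c_1=c_2\neq c_3$ (resynthesis-specific);
  IV $c_1\neq c_2=c_3$ (extraction change maintained).

The two rule sets differ because the series ask different questions (when
did the change arise vs. is it reversible), and the Group II definition
follows the change-arising-in-DTW-and-maintained reading (the alternative
reading — same state in the first and last genotype — is Pattern II's rule;
the two coincide only for triples with two distinct states).

## Design choices where the method is under-determined

* **Ties.** $\mathrm{rel}_A \in \{0.25, 0.75\}$ is exactly equidistant
  between two anchors. The package assigns the balanced category — the
  conservative choice toward the dominant pattern — then prefers A > B for
  the (unreachable on the simplex) remaining ties. Distances are rounded
  to 12 decimals before the argmin so that floating-point noise cannot
  flip an exact tie.
* **All-distinct ploidy triples.** A sequence with three pairwise distinct
  categories satisfies none of the four Pattern definitions verbatim. It
  is labelled III (the resynthesized hexaploid differs from its
  predecessor) and flagged in the `all_distinct` column so it can be
  tabulated separately. For the domestication rules the same triples fall
  under Group III by its literal definition and need no special handling
  (the test suite verifies all 27 triples for both rule sets against an
  independent enumeration).
* **"Statistically equal".** Balance is operationalised purely as
  nearest-anchor assignment; no secondary significance test is layered on
  top, since the distance computation is the method's complete definition.
* **TPM universe.** The TPM denominator uses *all* genes in the supplied
  count table, not only triad genes, matching per-sample library
  normalization before triad subsetting.
* **Gene position.** For zone assignment a gene is located at
  $\lfloor(\mathrm{start}+\mathrm{end})/2\rfloor$ in 0-based half-open
  coordinates (GFF3 input is shifted on read); which coordinate the
  original analyses used is unstated, and the midpoint is the only choice
  that is symmetric under strand.

## The statistical toolkit

All tests are implemented in the package (base R equivalents act as
independent cross-checks in the test suite):

* **Asymmetry.** Among biased triads, $k$ A-dominant out of $n$ biased is
  tested against Binomial$(n, 1/2)$, two-sided by the minimum-likelihood
  rule (sum of all outcomes no more likely than the observed one) — the
  convention of the standard exact test. The test is discrete: at
  $n = 200$ its achievable size at nominal $\alpha = 0.05$ is 0.040, which
  is what the calibration check measures.
* **Proportions.** Two-sample $\chi^2$ on 1 df with the Yates continuity
  correction on by default (capped at the observed difference).
* **Wilcoxon rank-sum** for modification-level comparisons: exact by full
  enumeration of rank assignments when $n_1+n_2 \le 20$ without ties
  (two-sided p is twice the smaller tail, capped at 1), otherwise the
  normal approximation with tie and continuity corrections. Replicates can
  be pooled by gene-wise means (default) or tested per replicate pairing.
* **Enrichment.** Upper-tail hypergeometric $P(X \ge k)$ per annotation
  term, with Benjamini–Hochberg q-values over all tested terms and a
  $q < 0.05$ significance flag. The default universe is all annotated
  genes supplied.
* **Concordance.** Modification labels × expression labels are crossed on
  the triads tracked in both assays. Each cell is tested by comparing the
  expression-label share inside the modification-label row against its
  share outside the row (a collapsed 2×2 proportion test). An alternative
  formulation — testing the observed cell share directly against the
  product-of-margins share with the same total as both sample sizes — is
  *not* used: the pooled two-sample variance badly overstates the variance
  of $\hat p_{ij} - \hat r_i \hat c_j$ under independence, making that
  test severely conservative; the row-in/row-out form is an asymptotically
  exact independence test. For the same reason the per-cell tests default
  to no continuity correction (they are used on tables with thousands of
  triads, where Yates' correction visibly distorts the null distribution
  of p-values; the correction remains available via `correct = TRUE`).

## The synthetic-data generator

`simulate_dataset()`/`simulate_series()` emulate the gene-level *products*
of a triad ChIP/RNA experiment, with recoverable planted truth:

* **Structure.** `n_triads` triads on chr1A/1B/1D plus background
  (non-triad) genes on chr2A/2B/2D; lengths uniform on 600–3000 bp; a
  five-zone partition (R1 15%, R2a 25%, C 20%, R2b 25%, R3 15%) per
  chromosome.
* **Categories.** Planted per (genotype, assay) by largest-remainder
  apportionment, so planted frequencies are exact rather than sampled —
  this is what makes frequency-recovery tests deterministic. Defaults
  emulate the magnitudes seen in tetraploid wheat: mostly balanced triads
  among the modified, a slight A-ward excess among biased ones, and
  unmodified fractions of roughly 20% (H3K4me3), 50% (H3K27me3) and 25%
  (RNA) per genotype.
* **Signal.** A modified triad's total TPM is
  $S = \max(5,\ 2\mu\,\mathrm{LogNormal}(-\sigma^2/2, \sigma))$ with
  $\mu = 30$ TPM and $\sigma = 1$, split $(S\,\mathrm{rel}_A,
  S\,(1-\mathrm{rel}_A))$ with $\mathrm{rel}_A$ uniform on [0.45, 0.55]
  (balanced) or [0.80, 0.95] (biased, mirrored for A < B). The log-normal
  spread reproduces the heavy-tailed TPM distributions of real data; the
  floor of 5 TPM keeps planted modified triads unambiguously above the
  0.5 TPM filter. Unmodified homoeologs draw uniformly on [0, 0.1] TPM.
  Hexaploid genotypes emit D-homoeolog signal at $S/2$ (used by the
  subgenome-share QC, ignored by classification); tetraploids emit none.
  Background genes absorb the remaining TPM mass, so planted TPMs are
  exact expected TPMs.
* **Counts.** Library size defaults to $10^6$ reads per 1000 triads.
  Expected counts are proportional to TPM × length, and replicates draw
  independently from a negative binomial with per-assay size $\phi$
  (variance $m + m^2/\phi$). On linear TPM the replicate Pearson
  correlation is bounded by $\phi/(\phi+1)$ whatever the between-gene mean
  distribution, so the defaults $\phi = 150$ (H3K4me3), 10 (H3K27me3) and
  20 (RNA) were chosen analytically to give replicate correlations near
  0.99, 0.90 and 0.95 respectively, mirroring the concordances typical of
  these assays.
* **Noiseless mode** ($\phi = \infty$) emulates the infinite-depth limit:
  the library is scaled 1000-fold and counts are rounded expectations.
  Without the depth scaling, integer quantization near the 0.5 TPM filter
  and the 0.75 boundary misassigns a small percentage of triads at
  moderate `n_triads` — a genuine loss of information at shallow depth,
  not an implementation artifact — and planted recovery could not be
  exact.
* **Series planting.** Label frequencies over I–IV are apportioned
  exactly; each labelled triad receives a canonical category sequence
  realizing its label (changed categories drawn uniformly from the other
  two). Unmodified triads are unmodified at all three genotypes, so the
  tracked subset realizes the requested frequencies exactly.

What the generator does **not** emulate: read-level artifacts (mapping
bias, duplicate reads), peak shape, spatial autocorrelation of chromatin
domains along chromosomes, correlated noise between marks, or
biologically coupled modification and expression states (assays are
planted independently unless labels are copied explicitly). Passing the
planted-recovery suite therefore demonstrates the correctness of the
pipeline's arithmetic and bookkeeping on data with known truth — not that
real wheat data meet the generator's assumptions.

## Numerical choices and degenerate inputs

* TPM columns sum to $10^6$ within $10^{-3}$ (asserted); the TPM oracle
  comparison uses $10^{-9}$ relative tolerance.
* A triad with both homoeologs at zero has undefined relative signal and
  is treated as unmodified; an all-zero sample is an error.
* Zero-variance replicate columns yield `NA` correlation with a warning.
* A proportion test with pooled proportion 0 or 1 reports p = 1 with a
  warning; the Wilcoxon degenerates to p = 1 when all values are tied.
* Category proportions must sum to 1 within $10^{-9}$; planted signal mass
  must leave at least 10% of the TPM budget for background genes.
* Problem sizes: module tests run at 40–2000 triads; the planted-recovery
  acceptance check runs 10,000 triads × 3 genotypes × 2 marks, the
  calibration checks use 10,000 null draws (asymmetry test) and 500
  simulated independence tables of 10,000 triads (concordance), and the
  acceptance script simulates 4000 triads per series × mark.

## Known limitations

* Only the two-subgenome (A/B) three-anchor scheme is implemented; the
  seven-category ternary classification used for three-subgenome analyses
  is out of scope, as are D-subgenome category tracking and series longer
  than three genotypes.
* The 0.5 TPM filter is absolute, so results depend on the TPM universe;
  supplying counts restricted to triad genes only will shift TPM scales
  and therefore filter outcomes.
* Whether gene-body or exon-union lengths are used for TPM is up to the
  supplied coordinates; the package treats the annotated span as the
  length.
* The exact binomial test's discreteness makes its realized size at small
  biased-triad counts noticeably below nominal; reported p-values are
  conservative there.
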