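---
title: "Models and methods behind medipdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind medipdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and the question

MeDIP (methylated DNA immunoprecipitation) enriches methylated DNA fragments
with a 5-methylcytosine antibody. On a two-channel promoter tiling array, the
bound (Cy5) over input (Cy3) intensity ratio of each probe is a relative
methylation score for its genomic position. The designs this package targets
tile every promoter from roughly 1000 bp upstream to 250 bp downstream of the
TSS at 100 bp spacing (13 probes per promoter), with three replicate arrays
per individual.

The scientific question is a two-group comparison — here generically "case"
vs "control" individuals (the motivating design contrasts 12 exposed against
28 unexposed adult males) — asking which promoters are differentially
methylated, whether the genome-wide answer is stronger than chance given the
group-size imbalance, and how the differential promoters organize along the
genome, across gene sets, and with respect to miRNA targeting.

## From intensities to methylation scores

Per array, the probe score is `log2(bound/input)`; values are missing where
either channel is non-positive, and probes missing in more than 20% of
arrays are dropped (the data do not justify imputing them; this default is
deliberately conservative). Arrays are forced onto a common distribution by
quantile normalization, under the assumption that total methylation is the
same in every sample. Our implementation replaces each column's sorted
values by the across-column mean of sorted values; tied values receive the
mean of the reference values their ranks span (order-independent), and
columns with missing values are mapped through linear interpolation of
quantiles. The transform is idempotent to floating-point precision.

Replicate arrays are averaged per individual *after* normalization, and all
group statistics are computed on the individual-averaged columns. Averaging
before modelling avoids treating the three replicates as independent
samples (pseudo-replication); running the model on all arrays instead is
possible by passing the un-averaged matrix with per-array labels, but the
averaged route is the default and the one the tests exercise.

Array-level QC summarizes the MvA cloud (M = log2 ratio, A = log2 product):
median and IQR of M, median A as a signal level, and the M-versus-A
correlation as a dye-bias symptom. A replicate-quality statistic reports the
fraction of variance among the 500 most variable probes explained by
individual rather than replicate; reproducible designs sit above 0.7.

## Probe tier: empirical-Bayes moderated t

For probe $g$, with group means $\bar y_{1g}, \bar y_{2g}$ and pooled
within-group variance $s_g^2$ on $d = n_1 + n_2 - 2$ degrees of freedom, the
effect is $\beta_g = \bar y_{1g} - \bar y_{2g}$ (case minus control, log2
units). Variances are shrunk toward a prior via the standard hierarchical
model $s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_d / d$,
$1/\sigma_g^2 \sim \chi^2_{d_0} / (d_0 s_0^2)$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
  \tilde t_g = \frac{\beta_g}{\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}},$$

with two-sided p-values from $t_{d_0+d}$ (standard normal when $d_0$ is
infinite). The hyperparameters are estimated by the closed-form moment
method on log variances: writing
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, the excess dispersion
$\mathrm{var}(e) - \psi'(d/2)$ equals $\psi'(d_0/2)$, solved by a
Newton-type trigamma inversion; then
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the empirical
dispersion does not exceed what sampling alone explains, $d_0 = \infty$ and
$s_0^2 = \exp(\bar e)$. Zero-variance probes are excluded from estimation
but still scored. The estimator is verified in the test suite against a
known scaled-inverse-chi-square prior and against an independent
implementation of the same moment method.

A probe is *called* differentially methylated when its moderated p-value is
below 0.05 **and** its absolute log2 fold-difference is at least 0.25. Both
thresholds are the screen's operating point, not adjustable significance
claims; the raw (unadjusted) p enters this rule.

## Promoter tier: shift test, FDR, and the two-tier call

Promoters are the inferential unit. The second tier asks whether a
promoter's probes are systematically shifted relative to the array: a
two-sided Wilcoxon rank-sum test of the promoter's moderated t-statistics
against all scored probes. The background deliberately includes the
promoter's own probes — 13 out of tens of thousands is a negligible
contamination and it keeps the background identical for every promoter.
With both samples of size at most 8 the p-value is computed by exhaustive
enumeration; otherwise by normal approximation with midrank tie correction
and a continuity correction. Because the genome-wide scan runs this test
for every promoter inside every permutation replicate, the scan is computed
in closed form from a single ranking of the array (exact for continuous
statistics; the generic path handles ties), and is verified probe-for-probe
against `stats::wilcox.test`.

Shift p-values are adjusted across promoters by Benjamini–Hochberg step-up,
once, jointly for both directions. The final calls are:

* **default**: the promoter contains a called probe *and* its shift-test
  FDR is below 20%;
* **strict**: a member probe passes p < 0.01 at the same fold-change cut
  *and* the shift FDR is below 5%.

The 20% FDR is a discovery threshold: the expected fraction of false calls
among the called promoters is about a fifth, which is appropriate for an
exploratory, set-level analysis and is exactly what the downstream
enrichment statistics condition on. The two criteria are applied
independently (no direction concordance is required between tiers; the
promoter's direction is taken from the shift tier's median comparison).
Each promoter is summarized by its *representative probe* — smallest p,
ties broken by larger |log2FC|, then probe id — and individuals can be
clustered on the representative probes of called promoters with Ward's
method (`ward.D2`) on 1 − Pearson correlation distance. Zero-variance
columns have undefined correlation; they are flagged and placed at
distance 1 from everything.

## Permutation null for the genome-wide count

Whether the number of called promoters exceeds chance — given the 12 vs 28
imbalance — is assessed by rerunning every label-dependent stage (group
model, hyperparameter estimation, moderated t, both call tiers) on random
partitions that assign exactly 12 individuals to the pseudo-case group.
Partitions are mutually distinct and never equal to the true labelling;
normalization and replicate averaging are label-free and stay outside the
loop. The reported percentile is the fraction of null counts *strictly*
below the observed count: ties count against the observed value, which is
conservative.

A subtlety matters for calibration checks: the call count is a discrete
statistic, and under a global null most datasets produce zero calls at BH
FDR 20% (for independent null p-values the chance of any BH rejection is
the nominal level, so roughly 80% of null datasets have a zero count). The
conservative percentile therefore piles up at 0 under the null and cannot
be uniform. The result object also carries `percentile_rand`, the standard
randomized percentile for discrete statistics,
$(\#\{\text{below}\} + U\cdot(\#\{\text{ties}\}+1))/(n+1)$ with
$U \sim U(0,1)$, which is exactly uniform under exchangeability; the test
suite uses it for calibration, while reported summaries keep the
conservative number.

## Enrichment statistics

All overlap questions use one primitive: the upper-tail hypergeometric
probability of drawing at least $k$ "interesting" genes in a set of $n$
from a universe of $N$ containing $K$. The universe is always the *measured*
universe — genes with at least one scored promoter — never the whole
genome. A gene is hypo-/hypermethylated if any of its called promoters has
that direction (a gene with conflicting promoters counts in both direction
universes, reflecting promoter-to-gene multiplicity).

* **Gene sets** (GMT input): three analyses per set — all differentially
  methylated genes, hypomethylated only, hypermethylated only — each with
  BH adjustment across sets.
* **miRNA-target consistency**: for each differentially methylated miRNA,
  its profiled targets are tested for enrichment of *hypomethylated* genes.
  A hypermethylated (putatively silenced) miRNA whose targets are
  coordinately hypomethylated is flagged "consistent" at target-enrichment
  FDR < 20% — the same discovery-FDR convention as the promoter calls.
* **Cell-type confound checks**: the overlap between the study's gene list
  and externally derived cell-type-specific lists, with "no confound"
  declared when p > 0.4. To compare probe-level designs, probes are paired
  across designs by mutual nearest neighbour within 150 bp (mutual-NN
  guarantees a 1-1 mapping; equidistant ties resolve toward the lower
  coordinate for determinism).

## Genomic organization

* **Window enrichment**: sliding windows (default 750 kb every 250 kb, both
  configurable; a variant treats each chromosome as one window) are tested
  by the same hypergeometric primitive against the genome-wide call rate,
  with BH across windows. Promoters belong to a window through their TSS —
  a single unambiguous point.
* **Distance correlation**: for every same-chromosome promoter pair within
  2 Mb, the representative-probe statistics enter the Pearson correlation
  of their 500 kb distance bin; both orientations of each pair are
  included, making the estimate symmetric. 95% CIs use the Fisher z
  transform with the unordered pair count; bins under 10 pairs are omitted.
* **CpG density**: the normalized CpG frequency of a promoter region is
  (observed CpG dinucleotides × length) / (#C × #G) — the observed count
  relative to what the region's own composition predicts; 0.6 is the
  conventional CpG-island mark. Group means for all/hyper/hypo promoters
  are compared by two-sided Welch t-tests (the safest default for unequal
  group sizes; the test behind reference values of this statistic is not
  standardized, so these p-values are descriptive).
* **Wiggle export**: per-probe case-minus-control differences are written
  as a UCSC variableStep track (1-based positions, span = probe length) for
  browser display.

## The synthetic data generator

Because the deposited raw arrays are not redistributable at desk scale, the
package ships a generator whose defaults *are* the study conditions: 12
case vs 28 control individuals, 3 replicate arrays each, 2000 promoters
(13 probes at −1000..+200) on two 50 Mb chromosomes, 5% of promoters
differentially methylated with 31% of those hypermethylated, 60 miRNA
promoters of which 12 are planted differential (75% hypermethylated) and 6
are target-consistent at sampling odds 5 with 50 targets each.

Mechanistically, the input channel is log-normal and the bound channel is
`input × 2^level`, where the level stacks: a per-promoter baseline (mean
0.5, SD 0.5 log2 units) with small per-probe jitter (SD 0.1) — promoter
coherence that gives the shift test something real to aggregate; the
planted effect δ (default ±0.5 log2, uniform across the promoter's probes —
the paper-scale magnitude of such effects is not published, so 0.5 is an
engineering choice giving per-probe power near, not at, saturation);
per-(probe, individual) biological noise (SD 0.4); per-array replicate
noise (SD 0.25); and an optional smooth intensity-dependent dye bias
(amplitude 0 by default, so MvA QC has something to detect only when asked
to). The noise SDs were fixed once so that roughly 70–75% of top-probe
variance is explained by individual, matching the replicate QC reported for
this design. Individual effects are independent across probes: making them
promoter-coherent would hand every null promoter a random shared shift,
destroying the shift tier's null calibration by construction — the
generator plants promoter coherence only in the baseline and the effect,
which is also all the promoter tier assumes.

Spatial structure comes from dense blocks (two 750 kb blocks of 25
promoters; 40% of planted promoters concentrate there with one coherent
direction per block), which drive both the window scan and the short-range
distance correlation. Promoter sequences, when asked for, come from a
first-order Markov chain whose C→G transition is solved so the realized
observed/expected CpG ratio matches per-class targets (defaults 0.86 for
hypomethylated, 0.42 overall, 0.38 for hypermethylated promoters).

What the generator does **not** emulate: scanner-level artifacts, probe
sequence effects, spatial-on-array structure, batch effects, cell-type
composition shifts, or any correlation between methylation and covariates.
Tests passing on this generator therefore demonstrate the statistical
machinery under its stated assumptions — normal noise, exchangeable
individuals, planted effects — not robustness to everything real arrays do.

## Numerical and design choices

* Everything is log base 2, matching the fold-change threshold's units.
* Genomic coordinates are 0-based half-open internally (BED convention at
  file boundaries); wiggle output is 1-based per its specification.
* Gene identifiers match exactly after upper-casing; alias resolution is
  out of scope.
* The trigamma inversion runs Newton steps to relative tolerance 1e-10;
  degenerate cases (no excess dispersion) fall back to the infinite-prior
  branch rather than a boundary estimate.
* `s2_tilde = 0` (possible only when both the prior and a probe's variance
  vanish) yields the smallest representable p-value and a degeneracy flag
  rather than NaN.
* BH is computed once across all shift-tested promoters; the strict tier
  reuses the same q-values at 5%.
* Window width/step default to 750 kb / 250 kb — megabase-scale regions on
  a quarter-megabase grid; both are knobs.
* Monte-Carlo problem sizes in the test suite (20 replicate datasets, 100
  permutation partitions, 2000 promoters) are the package's desk-scale
  operating point: large enough that the recovery statistics stabilize,
  small enough to iterate on.

## Known limitations

* No multi-factor designs, covariate adjustment, array weights, or
  replicate-correlation modelling in the probe tier; the design this
  implements controls confounders by sample selection.
* No within-array spatial or print-tip normalization.
* The permutation check permutes labels only; it conditions on the observed
  methylation matrix.
* Enrichment depends entirely on user-supplied gene sets and target maps;
  no ontology-graph propagation is attempted.
* Absolute call counts depend on array size and annotation version;
  cross-study comparisons should rely on the property-level behaviour
  (calibration, recovery, enrichment) rather than raw counts.
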