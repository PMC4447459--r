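---
title: "Two-stage screening with directional rank tests and random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage screening with directional rank tests and random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmwrf)
```

## The model

The package addresses expression studies with three *ordered* outcome
groups — healthy (H), non-aggressive (M) and aggressive (A) disease — where
single-probe tests reject so often that the significant set is not a usable
biomarker panel. Its core statistic is the probabilistic index over ordered
triples,

$$\hat P_{H,M,A;p} \;=\; \frac{1}{N_H N_M N_A}
  \sum_{i=1}^{N_H}\sum_{j=1}^{N_M}\sum_{k=1}^{N_A}
  I\!\left(x_{i,p;H} < x_{j,p;M} < x_{k,p;A}\right),$$

the empirical probability that one value drawn from each group falls in
strictly increasing order. Under exchangeability its expectation is 1/6;
under the stochastic ordering $F_H \prec F_M \prec F_A$ it is inflated
toward 1. `directional_test()` computes $\hat P$ for both orderings
(`H<M<A`, `A<M<H`) and a one-sided permutation p-value by permuting health
labels across all samples with group sizes fixed. The screen then
intersects the directional test with a repeated random-forest importance
ranking (`run_repeated_rf()`, `select_hi_probes()`): a probe is of *high
interest* (HI) when its smaller directional p-value is below $\alpha$
**and** its mean Gini importance ranks in the top `top_frac` of probes.
The intersection is what controls the size of the final panel; neither
filter is multiplicity-adjusted, and the companion
`bh_rejection_curve()` visualises what a Benjamini–Hochberg adjustment
would have rejected instead.

Assumptions worth stating: samples are treated as exchangeable under the
null even though family membership correlates profiles (the permutation
test is therefore approximate in pedigree data — see *Limitations*); the
indicator uses strict inequalities, so ties never count toward the index;
and the analysis stays at the probe level throughout — multiple probes of
one RNA are never aggregated, the target RNA is annotation only.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `B` | 5000 | label permutations per probe; the p-value floor is $1/(B+1)$ |
| `alpha` | 0.01 | directional-test threshold for significance and HI selection |
| `top_frac` | 0.10 | importance-rank fraction for HI selection |
| `R`, `T_trees` | 2000, 2500 | forest repetitions and trees per forest |
| `split` | 0.75 | training fraction of each stratified split |
| `half_window` | 500 kb | cis window half-width around the probe center (a "1 Mb window") |
| `alpha_eqtl`, `alpha_assoc` | 0.01, 0.05 | eQTL and Fisher-association thresholds |
| `k`, `linkage` | 3, complete | flat cluster count and linkage for sample clustering |

`R = 2000` and `T = 2500` reproduce the published analysis scale; all
desk-scale analyses, tests and the acceptance script in this repository use
`R = 50`, `T = 200` and `B = 500`, which this package treats as its
standard reduced profile — the statistics they estimate are the same, with
larger Monte-Carlo error.

## Numerical and procedural choices

* **Index computation.** $\hat P$ is computed by a compiled
  sort-and-scan kernel (counting, for each middle-group value, the
  group-1 values strictly below and group-3 values strictly above, with
  tie blocks processed jointly). Its output is exactly equal to the naive
  triple loop, which the test suite asserts on 1000 random instances.
* **Permutation p-values** use the add-one rule
  $p = (1 + \#\{b:\hat P_b \ge \hat P_{obs}\})/(B+1)$, so they are valid
  and never zero. When the number of distinct label assignments is at most
  10,000 the test switches to exhaustive enumeration and the p-value is
  exact. One permutation stream is shared across probes per ordering, so
  results are reproducible from one seed, and comparisons of $\hat P_b$
  against $\hat P_{obs}$ use a $10^{-12}$ slack to keep ties stable in
  floating point.
* **Two-group Mann–Whitney** (`two_group_mw()`, used for 2-genotype
  eQTLs): exact enumeration for $n_1+n_2 \le 12$ (tie-aware, half-weighted
  U), otherwise the normal approximation with tie correction.
* **Quantile normalization** maps each sample onto the cross-sample means
  of order statistics (via `limma::normalizeQuantiles`); tied values
  within a sample receive the mean of the reference values of their
  occupied ranks. The detection filter keeps probes detected in at least
  50% of the samples of at least one group and is applied before
  normalization; samples are taken as given (any sample-level QC is
  assumed done upstream).
* **Severeness** $S = \tfrac12 L_M + L_A$ maps certain-H/M/A calls to
  0 / 0.5 / 1. Per-sample profiles average $S$ over the runs in which the
  sample was held out, with reporting bands: positive above 0.6, negative
  below 0.4, undecided between.
* **Pooled ROC/AUC**: scores are per-sample averaged pooled likelihoods
  ($L_M + L_A$ against H, or $L_A$ against the rest); the AUC is the
  rank-statistic (trapezoidal) area with mid-rank tie handling.
  Per-run pooling is available via `per_run = TRUE`; averaging is the
  default because it matches per-individual severeness reporting.
* **Forest splits** are stratified per class (guaranteeing every class in
  training), `mtry` defaults to $\sqrt{P}$, depth unlimited.
* **Clustering** uses Kendall tau-b (tie-corrected) between sample
  profiles and $D = (1 - \tau)/2$; complete linkage is the default for
  correlation-distance clustering, and the ARI against the true status is
  computed at `k = 3` (the natural cut for three health groups; `k` is
  configurable since a 2-cut is equally defensible). A constant profile
  makes $\tau$ undefined and raises an error naming the sample.
* **eQTL tests** drop missing genotypes pairwise, exclude monomorphic
  SNPs, and exclude links where only singleton genotype groups remain.
  With three groups both directional alternatives (`0<1<2`, `2<1<0`) are
  computed and the smaller p-value is flagged with its direction; no
  combination rule is imposed, both values are reported.
* **Fisher 2×3** uses the exact conditional (Freeman–Halton) criterion —
  summing the probabilities of all tables with the observed margins that
  are no more probable than the observed one — after dropping all-zero
  genotype columns, so it reduces exactly to the 2×2 Fisher test when a
  genotype class is absent. Relatedness is deliberately ignored here,
  reproducing the standard practice for this design.
* **ANOVA comparator**: per-probe one-way fixed-effects F-test; the
  default reads `alpha = 0.001` as a Bonferroni-*adjusted* level
  (`adjusted = FALSE` switches to the per-test reading, since the
  published phrasing admits both). Zero-variance probes get p = 0 when
  group means differ, 1 otherwise.
* **Two-stage lasso (LRL)**: stage 1 separates H from pooled cases on all
  samples, stage 2 separates M from A on cases only, both standardized,
  on a 50-point log-spaced penalty grid spanning three decades below the
  data-derived maximum. When a `target_count` is given, stage 1 aims for
  half the budget (ties broken toward the larger penalty) and stage 2
  brings the combined count closest to the target; this keeps the
  healthy-vs-diseased stage from being emptied by the grid search while
  honouring the combined-count rule. `cv = TRUE` uses cross-validated
  deviance per stage instead.

## The synthetic cohort generator

`sim_config()` / `generate_cohort()` / `generate_genotypes()` emulate the
statistical structure the analysis assumes, with full ground truth. The
defaults are the study conditions: 78 / 79 / 36 samples in H / M / A, 547
probes, 20 planted ordered probes. On the log2 scale a value is

baseline(probe) + family effect + group shift + N(0, 1) noise,

with the planted shift 0, $\delta$, $2\delta$ along a direction randomized
per probe (so both orderings occur, as in real data where both up- and
down-regulated probes are found), $\delta = 1$ noise-SD by default.
Families (100 by default, effect SD 0.5) give relatives correlated
profiles. Detection is thresholded truth — undetected values remain
present numerically, as on background-subtracted arrays — at a 90%
overall detection rate. Genotypes are Hardy–Weinberg draws at MAF uniform
in (0.05, 0.5): each probe gets 15 cis SNPs within ±0.5 Mb plus one
just-outside negative control; planted eQTL SNPs add
$\beta \times$ (allele count) to the linked probe's log2 expression of
genotyped samples; planted associated SNPs shift the case allele frequency
to a target allelic odds ratio (2.5 by default) in both the discovery
(n = 54, case-enriched like a genotyped cancer subset) and validation
(n = 83) cohorts.

What the generator does *not* emulate: genotype sharing within families
(relatedness acts only through the expression family effect), linkage
disequilibrium between SNPs, batch or array effects, heavy-tailed
intensity noise, and missing expression values. Passing tests therefore
show that the machinery is correct and calibrated under a clean
generative model, not that the pipeline's operating characteristics
transfer to any particular real dataset.

## What the checks compute

The test suite's acceptance layer computes, among others: exact
equivalence of the fast index with the brute-force loop; the analytic
identities ($\hat P = 1$ under complete separation, the six orderings
summing to 1 on tie-free data, mean $\hat P = 1/6$ under the null); the
type-I error of the permutation test at $\alpha = 0.01$ on 2000 null
probes with the study's group sizes; recovery of planted probes by HI
selection (hypergeometric enrichment) and of planted eQTLs (lowest cis
p-value over 50 replicate cohorts); and the null AUC, which is averaged
over four independent null cohorts because a single cohort of this size
estimates a null AUC with a Monte-Carlo SD of about 0.04 — the average
pins the estimate down to about 0.02. The problem sizes above (2000 null
probes, $B = 500$, $R = 50$, $T = 200$, 4 null cohorts, 50 eQTL
replicates) are the package's standard desk-scale profile.

## Limitations

* The permutation null treats samples as exchangeable; with strong family
  effects the test is only approximately calibrated on pedigree data
  (the generator lets you quantify this directly).
* The HI rule's `top_frac` and `alpha` jointly control panel size but
  carry no formal error-rate guarantee; the BH rejection curve is the
  honest multiplicity picture.
* Permutation p-values are bounded below by $1/(B+1)$: ranking cis SNPs
  at small $B$ can tie at the floor.
* The Fisher association ignores relatedness, and the eQTL stage tests
  only HI probes — both reproduce the published design rather than
  improve on it.
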