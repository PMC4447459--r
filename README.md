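# gmwrf

Two-stage biomarker screening for ordered three-group expression studies:
a **g**eneralized **M**ann–**W**hitney directional test combined with
repeated **R**andom-**F**orest importance ranking.

## The problem

In familial cancer cohorts, expression profiles (here: probe-level miRNA
intensities from lymphoblastoid cell lines) are compared across three
*ordered* health-status groups — healthy (H), non-aggressive (M) and
aggressive (A) disease. Classical per-probe tests flag far too many probes
to be useful, so this package screens in two stages:

1. **Directional testing.** For each probe the probabilistic index

   P̂ = (1 / n_H n_M n_A) Σᵢ Σⱼ Σₖ I(x_{i;H} < x_{j;M} < x_{k;A})

   estimates the probability that a random triple, one value per group, is
   strictly increasing in the hypothesised order. It tests
   H₀: F_H = F_M = F_A against the stochastic ordering
   H₁: F_H ≺ F_M ≺ F_A (and the reverse ordering A ≺ M ≺ H), with a
   one-sided permutation p-value obtained by permuting group labels
   (default 5000 permutations, exact enumeration on small cohorts).

2. **Random-forest importance.** The cohort is repeatedly split 75/25 into
   training and test sets; each run grows a forest, records test-set class
   likelihoods and per-probe Gini importance. Probes with a directional
   p-value < 0.01 that also rank in the top 10% by mean Gini importance are
   the *high-interest* (HI) probes.

Around this core the package provides: the per-sample *severeness* score
S = ½·L_M + L_A with pooled ROC/AUC; Kendall-tau distance clustering of
samples on the HI probes with adjusted-Rand-index evaluation; cis-eQTL
mapping (±0.5 Mb windows, genotype-group rank tests) and Fisher exact
2×3 case–control association with replication in a validation cohort;
ANOVA and two-stage lasso-logistic comparator selectors; and a synthetic
cohort generator with planted ground truth so every stage is testable
without the original data.

## Worked example

Simulate a small cohort (60 samples, 50 probes, 5 planted ordered probes)
and run the whole pipeline:

```r
library(gmwrf)
cfg <- sim_config(n_H = 20, n_M = 22, n_A = 18, n_probes = 50, n_planted = 5,
                  delta = 1.5, n_snps_per_probe = 5, n_discovery = 30,
                  n_validation = 40, seed = 7)
pc <- pipeline_config(sim = cfg, B = 200, R = 20, T_trees = 100,
                      lrl_target = 6, seed = 42)
report <- run_full_pipeline(pc)
print(report)
#> Two-stage screening pipeline report
#>   n_samples                60
#>   n_probes_input           50
#>   n_probes_retained        50
#>   n_significant_HMA        4
#>   n_significant_AMH        2
#>   n_significant_probes     6
#>   auc_prca_vs_h            0.9894
#>   auc_a_vs_rest            0.9563
#>   n_hi_probes              5
#>   ari_hi                   0.3193
#>   n_cis_pairs_tested       25
#>   n_cis_significant        0
#>   n_anova_selected         4
#>   n_lrl_selected           6
#>   ari_anova                0.3140
#>   ari_lrl                  0.3225
```

Six probes pass the directional test at α = 0.01 (four increasing with
severity, two decreasing), five of which also make the importance cut and
become HI probes — all five are planted signal probes:

```r
print(report$hi)
#> 5 HI probes (p < 0.01 and importance rank in top 10%)
#>   probe_id min_p_value best_ordering mean_importance importance_rank
#> 1    P0027 0.004975124         A<M<H        3.255416               1
#> 2    P0039 0.004975124         H<M<A        2.803371               2
#> 3    P0020 0.004975124         H<M<A        2.521132               3
#> 4    P0026 0.004975124         H<M<A        2.516367               4
#> 5    P0048 0.004975124         H<M<A        1.678627               5
```

The AUCs (0.99 / 0.96) say the repeated forest separates cases from
controls and aggressive cases from the rest almost perfectly at this
planted effect size; `ari_hi` is the adjusted Rand index between the
3-cluster Kendall-distance clustering on the HI probes and the true
status. Individual stages are available directly:
`directional_test()`, `run_repeated_rf()`, `select_hi_probes()`,
`severeness_profile()`, `pooled_roc_auc()`, `kendall_distance_matrix()`,
`link_cis_snps()`, `eqtl_test()`, `fisher_2x3()`, `anova_screen()`,
`lrl_two_stage()`.

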