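# broodmeta

Phylogenetic multilevel meta-analysis of parent–offspring communication in
birds.

Comparative studies of begging ask what information chick signals carry and
what information parents actually use when allocating food — behavioural
begging, structural signals such as mouth colour, or body-size cues — and
whether the answer tracks a species' ecology: its brood-reduction strategy
and the current quality of the environment. Answering that requires pooling
hundreds of heterogeneous effect sizes across species that share ancestry.
`broodmeta` provides the complete pipeline for analysts doing this kind of
comparative meta-analysis:

* **Effect sizes** — conversion of t, one-df F, one-df χ², and
  means-and-SD statistics to correlations and Fisher's
  *Z* = atanh(*r*), with sampling variance *v* = 1/(*n* − 3) where *n* is
  the number of broods; mandatory direction for unsigned statistics.
* **Curation** — validated CSV loading with reject/exclusion ledgers, the
  brood-reduction decision rule (hatching asynchrony ≥ 24 h with biased
  mortality, or ≥ 75% of broods losing a chick), conservative
  environment-quality coding, and the ≥ 2 levels × ≥ 10 effects moderator
  gate.
* **The model** — for each relationship,

  *y* = *Xβ* + phylo + species + study + unit + error,

  a Gaussian multilevel meta-analytic model on the *Z* scale with a
  Brownian-motion phylogenetic correlation over species, independent
  species, study, and per-effect random effects, and *known*
  measurement-error variances from the brood counts. The fixed part is a
  no-intercept level-means parameterization (one mean per strategy, a
  linear environment slope, one slope-difference interaction), so the
  output table reads: level means, reduction difference, environment,
  interaction, grand mean. Fit by REML (analytic-gradient optimizer, GLS
  coefficients, Wald intervals) or by a conjugate Gibbs sampler (posterior
  means, equal-tailed credible intervals, pMCMC), and combined across a
  tree ensemble to propagate phylogenetic uncertainty.
* **Diagnostics** — multilevel *I*² partitioned across
  phylo/species/study/unit, and Egger's regression test of per-study mean
  effects against their pooled sampling variance.
* **Species summaries** — brood-weighted species means with
  *t*-based CIs and a positive/negative/null classification for forest
  plots and species counts.
* **Synthetic data** — a generator with known ground truth (Yule trees,
  phylogenetically correlated species effects, configurable variance
  components and moderators) plus a parameter-recovery harness reporting
  bias, RMSE, and interval coverage.

## Worked example

```r
library(broodmeta)

cfg  <- synthetic_config(seed = 42, n_species = 30)   # known ground truth
sim  <- simulate_dataset(cfg)
sim$dataset
#> Effect-size dataset: 159 effect sizes, 47 studies, 30 species

trees <- as_phylo_ensemble(list(sim$tree, simulate_tree(30, 1, 43)))
fit <- fit_relationship(sim$dataset, trees, "feeding_begging",
                        method = "mcmc", settings = mcmc_settings(seed = 1))
print(fit_table(fit), digits = 3)
#>                      term estimate   ci_lb  ci_ub     p
#> 1          brood_reducing   0.5634  0.1656 0.9742 0.009
#> 2    whole_brood_survival   0.2700 -0.1169 0.8365 0.146
#> 3    reduction_difference  -0.2934 -0.6354 0.0843 0.128
#> 4             environment   0.3935  0.2697 0.5181 0.001
#> 5 reduction_x_environment  -0.0547 -0.2272 0.1186 0.534
#> 6              grand_mean   0.4213  0.0585 0.8895 0.024
```

The generating truth was 0.5 and 0.2 for the level means, 0.35 for the
environment slope and 0 for the interaction: each estimate's 95% interval
covers its truth, the slope is recovered sharply (most records carry an
environment code of ±1), and `p` is the pMCMC zero-crossing probability —
the environment slope is clearly resolved, the interaction correctly is
not. `grand_mean` is the observation-weighted average of the two level
means at average environment.

```r
sub <- subset_relationship(sim$dataset, "feeding_begging")
i_squared(fit$vcomp, typical_sampling_variance(sub$data$v))
#> Total I2: 78.7%
#>   phylo    26.4%
#>   species  29.9%
#>   study    13.3%
#>   unit     9.1%

egger_test(study_average(sub))
#> Egger regression (variance predictor): z = -0.58, p = 0.563 (47 studies)

count_classes(summarize_species(sub, "feeding_begging"))[c("positive", "null", "total")]
#> $positive [1] 17   $null [1] 12   $total [1] 30
```

78.7% of the observed variance is true heterogeneity rather than sampling
error (the generator plants 4 × 0.05 of component variance against typical
sampling variances of ~0.08), the funnel shows no asymmetry (none was
simulated), and 17 of 30 species have individually resolvable positive
effects.

`run_all(dataset, trees, out_dir, config)` drives the same machinery over
every relationship in a dataset and writes per-relationship coefficient
TSVs, diagnostics JSON, species forest TSVs, and a checksummed run
manifest; `sensitivity_refit()` and `moderator_scan()` cover the
growth/mortality-exclusion refit and the methodological-moderator scans.

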