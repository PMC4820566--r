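---
title: "Models and methods behind broodmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind broodmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broodmeta)
```

## The scientific problem

Across bird species, chicks solicit food with behavioural begging and with
structural traits (mouth colour, UV reflectance, gape size), and parents
respond to begging, to structural signals, or to body-size cues — in
strikingly different ways in different species. Comparative meta-analysis
can ask whether this variation tracks ecology: whether a species' typical
brood-reduction strategy (shaped by environmental predictability) and the
current environmental quality predict who signals and what parents attend
to. `broodmeta` implements the full quantitative pipeline for such an
analysis: effect-size standardization, data curation, hierarchical
phylogenetic models, heterogeneity and publication-bias diagnostics, and a
synthetic-data module that makes every stage testable against known ground
truth.

## Effect sizes

Every reported statistic is converted to a correlation coefficient and then
to Fisher's Z:

* t statistics: `r = t / sqrt(t^2 + df)`;
* one-df F statistics: `|r| = sqrt(F / (F + df2))`, direction attached
  separately (multi-df F and chi-square statistics have no direction and are
  refused);
* one-df chi-square: `|r| = sqrt(chisq / N)`;
* group means and SDs: Cohen's d with the pooled SD, then
  `r = d / sqrt(d^2 + h)` with `h = (n1 + n2)^2 / (n1 n2)`.

`z = atanh(r)` is approximately normal with sampling variance
`v = 1 / (n - 3)`, where `n` is the number of **broods** — a unit that is
comparable across studies and conservative against pseudoreplication when
chicks or feeding visits were the reported unit. Rows with `n <= 3` have no
defined variance and are rejected at load, never imputed.

No small-sample (Hedges) correction is applied in the means route by
default: the conversion chain in this literature is conventionally applied
to the raw d, and the correction is below the resolution of brood-level
sampling noise at typical sizes. It is available as a flag.

The sign convention is behavioural: positive means chicks signalling more
(or in better condition) received more of the outcome. Unsigned statistics
must come with a reported direction; a missing direction is an error rather
than a silent positive, because sign errors are the most damaging and least
detectable curation failure in a meta-analysis.

## Curation rules

* **Brood-reduction strategy.** A species is brood reducing when hatching is
  asynchronous (24 h or more between first and last chick) *and*
  later-hatched nestlings die at a greater rate; when either of those is
  unknown, the fallback criterion is that at least 75% of broods typically
  lose at least one chick to starvation. Everything else is whole-brood
  survival; a species with no information cannot be classified and must be
  excluded. The classifier takes one consolidated input per species: when
  sources conflict across populations, reconciling them is a judgement call
  for the analyst, not the software.
* **Environment quality** is an ordered three-level factor coded −1/0/+1
  (worse than normal / normal / better than normal). Records with no
  information are conservatively coded normal.
* **Eligibility filters.** Hunger-only condition measures are excluded from
  the condition–signal relationships (hunger is not long-term condition),
  but *not* from the feeding relationships, whose analyses assume nothing
  about what information a signal carries. Records where begging and size
  cues cannot be separated, and single-egg species, are excluded. Every
  removed record carries exactly one reason in an exclusion ledger, and
  `kept + excluded = input` is asserted on every run.
* **Moderator gate.** A methodological moderator is analysed only when at
  least two of its levels have at least 10 effect sizes.

## The hierarchical model

For one relationship, the Fisher-Z effects are modelled as

y = Xβ + Z_s p + Z_s s + Z_u t + u + e,

with fixed effects in the no-intercept level-means parameterization — one
mean per brood-reduction strategy, a linear environment slope, and one
interaction column attached to the whole-brood-survival level, so the
interaction coefficient is directly the difference in environmental slopes
between strategies, matching the row structure of a strategy-by-environment
results table. The contrast coding of the original analyses is not public;
this choice is one consistent reading and is recorded in output metadata.
The derived rows are `reduction_difference` (WBS minus BR) and
`grand_mean`, the observation-weighted average of the level means at
average environment. Observation weighting (rather than species weighting)
matches the weighting of the likelihood itself; this too is a documented
choice rather than a published fact.

Random effects: `p` are species effects correlated by the Brownian-motion
correlation matrix `C` of the phylogeny (variance σ²_phylo), `s`
independent species effects (σ²_species), `t` study effects (σ²_study),
`u` per-effect "unit" effects (σ²_unit), and `e` has *known* diagonal
covariance `diag(v)` from the brood counts — the defining feature of a
meta-analytic model: measurement-error variances are data, never estimated.
Keeping both species-tied terms honours the separation between shared
ancestry and species-specific repeatability; with few studies per species
they can be weakly identified, in which case boundary estimates are
reported, not suppressed.

`C` is built from shared root-to-tip path lengths,
`C_ij = V_ij / sqrt(V_ii V_jj)`. The correlation (not covariance)
parameterization makes every estimate invariant to rescaling all branch
lengths — so whether trees were scaled to unit height is immaterial, which
is exactly why the correlation form was chosen. Non-ultrametric trees are
handled by the per-pair normalization rather than forced
ultrametricization, preserving the input data. When an ensemble is pruned
to the study species, the stem below the subset's most recent common
ancestor is retained as a root edge, so shared-ancestry depths are measured
from the original root and pruning commutes with correlation construction.

### REML

The deterministic estimator maximizes the restricted likelihood over the
four non-negative variance components (L-BFGS-B with analytic gradients,
two starts) and solves generalized least squares for β at the optimum. The
restricted likelihood is implemented in Harville's form, including the
`log|X'X|` constant, so its value equals the log-density of an orthonormal
basis of error contrasts — which is how the test suite checks it against a
brute-force dense multivariate-normal oracle to 1e-8. Wald intervals are
reported for β; variance components get Wald intervals from the numerically
differentiated REML Hessian, truncated at zero and flagged at the boundary.

### Gibbs sampling

The Bayesian fit mirrors the model with conjugate updates: the fixed
effects and each random-effect block are drawn from their exact Gaussian
full conditionals, then each variance component from its scaled
inverse-chi-square full conditional (prior scale 1, 0.002 degrees of
belief — the conventional weakly informative default for this model
family). Blocked updates were chosen over one joint location update
deliberately: the joint update needs a large factorization per sweep, while
the blocked sweep costs one small species-by-species factorization plus
vectorized scalar updates, and targets the same posterior. The slowest
mixing direction is the split between the two species-tied effects, which
does not contaminate the fixed-effect summaries (those depend on the sum).

One block needs special care. The per-effect unit effects compete directly
with the *known* sampling variances: each u_i is individually almost
unidentified, so alternating "u given σ²_unit" with "σ²_unit given u"
leaves σ²_unit nearly frozen at any affordable run length, and its
posterior quantiles come out too narrow (measured as ~86–88% coverage of
nominal 95% intervals in recovery experiments, at both 6,000 and 13,000
iterations). The sampler therefore draws the pair as one partially
collapsed block: σ²_unit first from its conditional with u integrated out —
given the other effects the residuals are independent N(0, v_i + σ²_unit),
a one-dimensional target sampled by slice sampling on log σ² — and u then
from its exact Gaussian conditional. By the chain rule this is a draw from
the joint conditional of (σ²_unit, u), so the stationary distribution is
unchanged while the autocorrelation of σ²_unit collapses; the same
recovery experiment then shows all components inside the coverage band.
Defaults are 13,000 iterations, 3,000 burn-in, thinning 10. Point estimates
are posterior means; intervals are equal-tailed 2.5/97.5 percentiles
(deterministic given the samples, unlike HPD intervals); `pMCMC` is the
doubled smaller tail count, floored at 2/N, with exactly-zero samples in
neither tail.

### Tree ensembles

Phylogenetic uncertainty is propagated by fitting the model on each tree of
an ensemble — comparative studies commonly draw 100 candidate trees from a
pseudo-posterior tree distribution — and pooling: MCMC samples are concatenated with equal weight;
REML estimates are averaged with total variance equal to mean within-tree
variance plus between-tree variance. Per-tree MCMC seeds are derived
deterministically from the run seed, so a rerun reproduces every draw.

## Diagnostics

**I².** The typical sampling variance uses the higher-order-weights
definition `s² = ((k−1) Σw) / ((Σw)² − Σw²)`, `w = 1/v` — standard practice
when variances are unequal. Total I² is the summed
phylo/species/study/unit variance over that sum plus `s²`, reported as a
percentage, with per-component shares on the same denominator so they add
up to the total. The partition is invariant to common rescaling of all
variances.

**Egger's test.** Study-level effects are the unweighted mean of each
study's z values with pooled variance `1/(Σ broods − 3)`; the regression of
effect on sampling **variance** with weights 1/variance follows the framing
"average effect size per study compared with its variance" (an SE-predictor
variant is available for cross-checks against the classical test). The
statistic is slope/SE against a normal reference. At 40-study scale this is
mildly anticonservative relative to a t reference — measured rejection at
the 5% level is about 0.06–0.07 on unbiased funnels, inside the tolerance
this package asserts in its tests.

**Species summaries.** Species means are brood-weighted (consistent with
the model's weighting; the within-species weighting behind the published
forest plots is not stated), with `se = 1/sqrt(Σ broods − 3)` and a t
critical value on `Σ broods − 3` degrees of freedom — the same df
convention as the Fisher-Z variance. A species is positive/negative when
its CI excludes zero, null otherwise; this CI rule is an approximation to
whatever per-species rule produced published species counts, and is
flagged as such.

## The synthetic-data generator

The generator is the package's ground truth, not a tuning knob. Defaults
emulate the shape of this literature: 60 species on a Yule tree, ~1.5
studies per species, ~3 effect sizes per study, brood counts from a shifted
negative binomial with mean 15 (minimum 5, so every variance exists),
environments poor/normal/good with probabilities 0.25/0.5/0.25, and half
the species brood reducing (optionally thresholded on a Brownian trait so
strategy clusters on the tree, the worst case for separating strategy from
phylogeny). Fixed effects default to level means 0.5 and 0.2, an
environment slope of 0.35 and a null interaction — magnitudes in the range
of published Z-scale coefficients, with the null interaction doubling as
the calibration target for pMCMC. Each variance component defaults to 0.05:
substantial heterogeneity (total I² around 70% against a typical sampling
variance of ~0.08), typical of behavioural meta-analyses, and large enough
that component recovery is a meaningful test rather than a boundary pile-up.

Noise is added on the Z scale — the scale on which the model assumes
normality — and r back-computed as tanh(z), so no simulated record can
violate |r| < 1. Simulating on r and transforming would distort the
assumed error structure.

What the generator does *not* emulate: real phylogenies (it uses pure-birth
trees), correlations between moderators and species, non-Gaussian effect
distributions, selective reporting, or dependence of brood counts on
species. Passing recovery tests therefore demonstrates the estimator is
correct under its own assumptions, not that those assumptions hold in any
real dataset.

## Validation choices and problem sizes

The test suite checks, among other properties: exact agreement (1e-8) of
the restricted likelihood and GLS coefficients with a dense
multivariate-normal oracle on 20 random small instances; exact collapse to
the inverse-variance weighted mean when all components are pinned to zero;
95% interval coverage within a [90%, 99%] binomial band for all eight
parameters over 200 simulate-and-refit replicates at the default realistic
scale, using the Bayesian fit (its intervals propagate variance-component
uncertainty, which Wald REML intervals ignore — the level means are the
parameters that expose the difference); Egger rejection rate in
[0.03, 0.08] over 500 unbiased funnels; uniformity of pMCMC under a
true-null coefficient over 200 replicates (Kolmogorov–Smirnov p > 0.01);
and byte-identical reruns of the full pipeline, MCMC included, under fixed
seeds. Recovery and calibration replicates run the sampler at 4,000
iterations (1,000 burn-in, thinning 3) — with the collapsed variance
updates the thinned draws are close to independent, so this run length
keeps the full validation suite a desk-scale computation while effective
sample sizes remain adequate for 95% intervals; the default
13,000-iteration settings are for single analyses.

## Known limitations

* Gaussian responses only; no odds-ratio or hazard-ratio conversions (the
  begging literature does not report them).
* The two species-tied variance components are weakly identified when most
  species contribute one study; their *sum* (and hence β and total I²) is
  well estimated, the split less so.
* REML Wald intervals for level means can slightly undercover at ~60
  species; use the Bayesian fit when interval calibration matters.
* The per-species positive/negative/null classification depends on a CI
  rule the original figure legends do not fully specify.
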