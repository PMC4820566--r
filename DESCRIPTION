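Package: broodmeta
Title: Phylogenetic Multilevel Meta-Analysis of Parent-Offspring Communication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A comparative meta-analysis toolkit for studies of begging,
    structural signals and parental food allocation in birds. Converts
    reported test statistics into Fisher's Z-transformed correlation
    coefficients with brood-count sampling variances, fits hierarchical
    meta-analytic models with phylogenetic, species, study and unit random
    effects by restricted maximum likelihood or a conjugate Gibbs sampler,
    combines fits across ensembles of candidate phylogenies, partitions
    heterogeneity (I-squared) across random-effect levels, runs Egger's
    regression test for funnel-plot asymmetry, and summarises species-level
    pooled effects. A synthetic-data module generates trees and effect-size
    datasets with known ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
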