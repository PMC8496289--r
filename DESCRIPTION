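Package: qxescan
Title: Mixed-Model GWAS for QTL-by-Environment Interactions in Multi-Trial Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association scans for quantitative trait loci (QTL)
    and QTL-by-environment (QxE) interactions in multi-environment,
    multi-trial experiments. Fits unified linear mixed models whose random
    effects combine genomic-relationship (G), genotype-by-environment (GxE)
    and genotype-by-trial (GxT) covariance kernels into a single integrated
    kernel with variance-component weights estimated by average-information
    REML. Marker effects are parameterised as additive-main, AMMI-type
    (main plus per-environment deviations) or GGE-type (one coefficient per
    environment) fixed terms and tested by likelihood-ratio and Wald tests,
    with q-value based significance calls and genomic-inflation diagnostics.
    Includes a calibrated phenotype simulator for canonical reaction-norm
    patterns (persistence, divergence, convergence, crossover), a structured
    genotype generator, and recall/precision/AUC model-evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
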