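Package: cloneGP
Title: Genomic Prediction of Clonal Performance with Non-Additive Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction for clonally propagated crops (sugarcane-like
    breeding programs) exploiting non-additive genetic effects. Builds
    additive and dominance relationship matrices under the natural and
    orthogonal interactions (NOIA) parameterization from observed genotype
    frequencies, Hadamard-product epistatic kernels, genome-wide
    heterozygosity covariates, and Gaussian kernels; fits nested GBLUP and
    extended-GBLUP mixed models by average-information REML with
    likelihood-ratio model comparison; fits Bayesian reproducing kernel
    Hilbert space (RKHS) regressions by Gibbs sampling; and evaluates
    forward-prediction accuracy by region. Includes a synthetic-data
    generator emulating a multi-region, multi-year clonal trial system with
    controlled additive, directional-dominance and additive-by-additive
    epistatic variance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
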