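Package: asymmeta
Title: Multi-Site Meta-Analysis and Heritability of Brain Volumetric Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-level pipeline for studying left-right volumetric
    asymmetries of bilaterally paired brain structures across many
    imaging sites. Within each site it computes asymmetry indices
    AI = (L - R)/(L + R), applies an adaptive standard-deviation outlier
    rule, residualises covariates, and derives Welch sex/handedness
    contrasts, ANCOVA age coefficients, and one-sample lateralization
    tests. Site summaries are pooled by DerSimonian-Laird random-effects
    meta-analysis with Cochran's Q, Higgins' I-squared, Rosenberg's
    weighted fail-safe N, and a weighted meta-regression on median ages.
    Between-dataset and software-version heterogeneity is quantified as
    eta-squared variance shares. Pedigree-based variance-component models
    estimate the heritability of asymmetry indices and the genetic
    correlation between left and right volumes, with boundary
    likelihood-ratio tests. A synthetic-data module generates multi-site
    subject tables and extended pedigrees with known effect structure so
    every stage is testable without access to consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
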