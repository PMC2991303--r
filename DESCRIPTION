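Package: episcreen
Title: Exhaustive SNP-SNP Interaction Screening for Quantitative Traits in Sibship Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for characterizing the genetic architecture
    of an adjusted quantitative trait in family (sibship) samples. Stage I runs
    exhaustive single-SNP, SNP-covariate and SNP-SNP interaction scans with
    nested least-squares models and partial F-tests on covariate- and
    admixture-adjusted log-trait residuals. Stage II reduces false positives
    with three pre-determined criteria: false discovery rate q-values, repeated
    four-fold cross-validated incremental prediction R-squared, and internal
    replication across two sibling subsets, followed by a homogeneity check.
    Passing interactions feed a forward-selected multivariable model with a
    mixed-model sensitivity analysis for familial correlation. A sibship-aware
    genotype/phenotype simulator with two-way admixture and embedded epistatic
    effects makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
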