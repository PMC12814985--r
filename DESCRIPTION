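Package: kaptwas
Title: Kernel-Based Transcriptome-Wide Association Testing of Alternative
    Polyadenylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage gene-level association testing for alternative
    polyadenylation (APA). Per-gene penalized regression models (ridge-BLUP,
    elastic net, LASSO, single-best-SNP) are trained with five-fold
    cross-validation to estimate SNP effects on distal poly(A) site usage
    (PDUI); the selected model's coefficients then weight a linear genotype
    kernel whose quadratic-form score statistic is tested against a mixture
    of chi-squares null distribution, capturing additive and non-additive
    genetic effects. Includes the linear weighted z-score APA-TWAS baseline,
    PLINK and TSV genotype handling with quality control, a simulation
    framework spanning additive, single-variant, epistatic, heterogeneous
    and compensatory architectures under causality and pleiotropy
    assumptions, liability-threshold binary traits, and power / type-I-error
    evaluation drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
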