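Package: nbdep
Title: Cancer Self-Dependency Detection from shRNA-Level Viability Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects cancer self-dependencies directly from shRNA-level
    viability (log fold-change) scores of pooled RNAi screens, without
    aggregating reagents into gene-level scores. The pipeline removes pool
    and seed thermodynamic-stability batch effects by per-cell-line
    regression, ranks corrected scores within each cell line, selects the
    concordant half of each gene's shRNAs by correlation with the gene's
    average rank profile, and tests the association between a gene's
    alteration status (missense, non-missense, amplification) and the
    viability ranks of its shRNAs with a negative binomial random-intercept
    mixed model fitted by Laplace or adaptive Gauss-Hermite approximation.
    Includes a synthetic screen generator and Monte Carlo type-I-error and
    statistical-power protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    MASS,
    glmmTMB,
    lme4,
    limma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
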