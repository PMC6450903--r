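Package: indexbias
Title: Correction of Index Event Bias in Genome-Wide Association Studies of
    Disease Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association studies of prognosis, severity or
    survival select subjects on disease status, which induces collider
    (index event) bias: causes of disease become spuriously associated
    with subsequent outcomes. This package estimates the confounding
    slope from the regression of conditional prognosis effects on
    incidence effects across LD-pruned variants, corrects it for
    regression dilution (Hedges-Olkin or simulation extrapolation with
    bootstrap confidence intervals), and applies the correction to every
    variant with propagated standard errors and p-values. It also
    includes reading and harmonisation of GWAS summary statistics,
    greedy LD pruning, empirical bootstrap inference for focal variants,
    genomic-control diagnostics, and a simulation engine (individual
    level and summary level) for liability-threshold, case-only and
    survival designs to study the operating characteristics of the
    adjustment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    lmtest,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
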