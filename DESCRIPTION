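Package: qtlmm
Title: Mixed-Model QTL Mapping and Association Analysis in Line Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Linear mixed models for quantitative trait locus (QTL) mapping
    and marker association analysis. Fits models combining fixed effects,
    polygenic and user-defined random effects and QTL effects (additive,
    dominance, imprinting, epistasis) in two-line crosses (F2, F3,
    backcross) and general pedigreed populations. Builds pedigree (A,
    A-inverse) and marker-based (raw and standardized genomic) relationship
    matrices, computes line-origin probabilities along chromosomes with a
    hidden Markov model under the Haldane map function, estimates variance
    components by EM-REML through Henderson's mixed-model equations, and
    performs likelihood-ratio scans, per-SNP association tests and
    conditional linkage-versus-linkage-disequilibrium comparisons. Includes
    a seed-controlled simulator of line-cross data and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite
Config/testthat/edition: 3
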