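Package: seedstress
Title: Germination, DNA-Damage and Expression Phenotyping of Primed Seeds
    Under Heat Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for factorial seed-priming and heat-wave
    experiments in legumes. Computes germination kinetics indices
    (germinability and mean germination time), seedling phenotype
    frequencies and biometry summaries, alkaline comet-assay arbitrary-unit
    DNA-damage scores from visually scored nucleoid class counts,
    efficiency-standardized qPCR relative expression with geNorm
    reference-gene stability ranking, Welch t-tests, one-way ANOVA with
    Duncan's multiple range test and compact letter displays, and Z-score
    PCA of the combined phenotype and expression variables. Includes a
    synthetic-data generator emulating the unprimed/hydroprimed by
    unstressed/heat-wave factorial design so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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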