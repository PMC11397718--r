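Package: pollenphen
Title: Pollen Phenotype Statistics for Infrageneric Germplasm Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistics for replicated pollen-morphometric trait tables of
    congeneric germplasm collections (species and cultivars): intraspecific
    uniformity and interspecific distinctness coefficients of variation,
    per-trait one-way ANOVA with Tukey HSD compact letter displays,
    Erdtman-style size and shape classification, standardized hierarchical
    clustering with a two-level group/subgroup cut, pedigree-aware family
    aggregation and perforation-density progression scores, hybridization
    frequency analysis, ordinal evolutionary-trend correlations, and a
    seeded synthetic-data generator with midparent inheritance for testing
    the whole pipeline without raw measurements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
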