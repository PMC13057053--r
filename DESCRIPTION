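Package: seedqtl
Title: Germination Indices, Multi-Trait Selection and Single-Marker QTL
    Analysis for Doubled-Haploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-side analysis pipeline for seed-germination and
    seedling-establishment experiments on biparental doubled-haploid (DH)
    populations under osmotic (drought) stress and seed-priming treatments.
    Computes 22 germination and seedling indices (final/initial germination
    percentage, mean germination time and rate, germination pace, synchrony,
    uncertainty, vigor index, drought-tolerance indices and reductions) from
    daily count data; fits balanced random-genotype ANOVA models with
    variance components and broad-sense heritability; ranks genotypes with
    the multi-trait genotype-ideotype distance index (MGIDI) via factor
    analysis with varimax rotation; and runs single-marker QTL scans with
    LOD scores, phenotypic variance explained, additive effects,
    permutation-based genome-wide thresholds and 1-LOD support intervals on
    a Kosambi-scaled linkage map. A seeded simulator generates linkage maps,
    DH genotypes, planted additive QTLs and per-seed germination
    time-courses with the same statistical structure, so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
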