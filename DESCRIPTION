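Package: domdev
Title: Dominance-Deviation Association Testing for Quantitative and Binary Traits
Version: 0.1.0
Authors@R: person("Exeter", "Genetics Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Genome-wide dominance-deviation (0/1/0 heterozygote term) association
    analysis for quantitative and binary traits, with the variant QC filters
    (imputation info, Hardy-Weinberg exact test, minor allele frequency),
    phenotype preparation (BMI measure reconciliation, covariate
    residualisation, rank inverse-normal transform, obesity and type 2
    diabetes case definitions), grouped-statistics reproduction of
    genotype-class tables, fixed-effects meta-analysis, Bonferroni threshold
    derivation and non-central chi-square power calculations used in
    biobank-scale studies of non-additive genetic effects. Includes a
    synthetic-cohort generator producing imputed genotypes (VCF with GT/DS)
    and phenotype tables with planted additive and dominance-deviation
    effects, so the full pipeline is testable without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    VariantAnnotation
Config/testthat/edition: 3
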