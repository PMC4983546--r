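Package: polycomorb
Title: Polygenic Risk Scores and General Substance-Involvement Liability
Version: 0.1.0
Authors@R:
    person("Polycomorb", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for testing whether polygenic liability to
    psychiatric disorders is shared with substance involvement. Builds
    thresholded, LD-clumped polygenic risk scores (PRS) from GWAS summary
    statistics and target-cohort genotypes; derives a standardized general
    substance-involvement factor (GENSUB) from five ordinal substance
    measures by one-factor confirmatory factor analysis; tests PRS-phenotype
    associations with ordinary least squares and baseline-category
    multinomial logistic regression including 1-df Wald odds-ratio equality
    contrasts; and controls the correlated family of tests with a
    label-swapping max-statistic permutation threshold. A synthetic-cohort
    generator with LD-blocked genotypes and a latent-factor involvement
    model stands in for restricted-access data so that every stage is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
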