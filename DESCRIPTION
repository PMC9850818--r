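Package: cisconstraint
Title: Constraint-Aware Prioritization of Interspecies Allele-Specific
    Expression Differences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks genes by comparing each gene's interspecies (hybrid)
    allele-specific expression to its within-species population ASE
    distribution with a Mann-Whitney U test, so that expression changes
    between species are weighed against the cis-regulatory variation
    tolerated within a species.  Provides signed and difference-in-ranks
    gene rankings, a self-contained preranked gene-set enrichment engine
    (weighted Kolmogorov-Smirnov running sum with a gene-permutation
    null), and a binomial sign test on enrichment-driving genes to detect
    lineage-specific polygenic selection on cis-regulation.  Includes a
    beta-binomial simulator of population cohorts and hybrid experiments,
    validation procedures (constraint-score correlation, down-sampling,
    expression-matched comparison, cohort-split robustness), and readers
    and writers for allele-count TSV and GMT gene-set formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
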