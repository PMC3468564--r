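Package: trioscan
Title: Lineage-Specific Substitution Screens on Human-Chimp-Outgroup Codon Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens protein-coding genes for an excess of nonsynonymous
    substitutions on the human lineage using human-chimpanzee-outgroup codon
    trios. Builds in-frame codon alignments by protein-level alignment and
    back-translation, assigns synonymous and nonsynonymous changes to lineages
    by outgroup-polarized parsimony pathway counting and by maximum likelihood
    under a codon substitution model with branch-specific dN/dS, and ranks
    genes by the excess-nonsynonymous statistic. Downstream population-genetic
    stages type multi-site haplotypes into allele classes, compute
    Hardy-Weinberg genotype expectations and chi-square tests for three-allele
    systems, and fit the relative-head-size genotype association with
    dominant-coded sequential ANOVA. Ships seedable simulators for codon trios
    evolved under the model, Hardy-Weinberg genotype panels, and phenotype
    tables with planted genotype effects, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'genetic-code.R'
    'codon-model.R'
    'alignment.R'
    'parsimony.R'
    'likelihood.R'
    'simulate.R'
    'popsim.R'
    'toy-m003.R'
    'popgen.R'
    'scan.R'
    'association.R'
    'io.R'
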