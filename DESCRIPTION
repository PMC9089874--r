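Package: famseg
Title: Pedigree-Aware Rare-Variant Filtering and Segregation Analysis for
    Multiplex-Family Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for whole-exome analysis of multiplex
    families: genotype- and site-level quality control, KING-robust
    kinship verification against pedigree-expected relationship degrees,
    rare-variant filtering on functional consequence, population allele
    frequency, gene intolerance (RVIS percentile) and brain expression,
    per-pedigree inheritance-pattern classification (variants shared
    among affected members, de novo, recessive homozygous, X-linked
    hemizygous), candidate-set construction, and hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction.  Includes a
    fully ground-truthed synthetic cohort generator (multi-sample VCF,
    pedigree, annotation tables, gene sets) so every stage is testable
    without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
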