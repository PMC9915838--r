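Package: hippotrio
Title: Trio-Aware Rare-Disease Variant Triage with Panel-Agnostic and
    Panel-Based Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritises short variants from annotated rare-disease trio
    sequencing data under two competing strategies: a panel-agnostic filter
    that retains variants of high pathogenic potential using population and
    cohort allele frequencies, CADD and SpliceAI scores, ClinVar assertions
    and trio segregation (de novo, biallelic and compound-heterozygous
    searches), and a gene-panel tiering strategy modelled on the NHS Genome
    Medicine Service workflow (Tier 1/Tier 2 in green panel genes, a
    gene-agnostic de novo and Exomiser channel, and a Tier A copy-number
    rule).  Includes a declarative reporting exclusion-criteria engine,
    diagnostic-efficiency comparison statistics (rates per variant assessed
    and paired Wilcoxon signed-rank tests), a deterministic synthetic trio
    cohort generator for end-to-end validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
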