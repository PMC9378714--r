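Package: colocscreen
Title: Proteome-Wide Bayesian Colocalisation Screening of Molecular QTLs
    Against Disease GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genetically informed protein-prioritisation pipeline for GWAS
    summary statistics. Implements Wakefield approximate Bayes factors and
    five-hypothesis Bayesian colocalisation between a molecular QTL trait
    (e.g. a plasma protein) and a disease outcome, with prior-sensitivity
    grids, LD-based robustness guards (instrument representation and sentinel
    concordance), a three-tier significance classification, single-instrument
    Wald-ratio Mendelian randomisation, multi-trait colocalisation with
    divisive cluster discovery, single-signal fine-mapping with stepwise
    cross-ancestry prior transfer, approximate conditional adjustment of
    regional summary statistics, LD computation from reference genotype
    panels, and a synthetic-data generator for regional summary statistics
    under null, distinct and shared causal-variant scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
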