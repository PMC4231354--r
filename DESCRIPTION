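Package: bifidotyper
Title: Polyphasic Typing and Semi-Quantitative Enumeration of Dairy
    Bifidobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for polyphasic identification and
    enumeration of bifidobacteria in raw-milk cheese surveys. Implements
    in-silico PCR-RFLP species typing (amplicon extraction, restriction
    digestion, gel-pattern matching and combination-based species calls),
    semi-quantitative counts from enrichment dilution series with grouped
    survey summaries, DNA-DNA relatedness from renaturation kinetics and
    G+C content from thermal melting curves, multilocus sequence analysis
    (allele assignment, sequence types, concatenated-gene neighbor-joining
    trees), and phenotypic numerical taxonomy (Jaccard similarity, UPGMA
    dendrograms). A synthetic-data module generates inputs with known
    ground truth for every stage so the whole pipeline can be exercised
    and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
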