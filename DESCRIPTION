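Package: aarules
Title: Frequent Amino-Acid Patterns and Association Rules in Protein
    Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines frequent contiguous amino-acid patterns from protein
    sequences by partitioning each sequence into fixed-length windows,
    treating the windows as market-basket transactions and running the
    levelwise Apriori algorithm over the 20-letter amino-acid alphabet.
    Association rules derived from the frequent itemsets are filtered by
    confidence and then pruned with the objective interestingness
    measures lift, bi-lift, bi-improve and bi-confidence, isolating the
    positively correlated ("useful") rules that describe dominating
    residue patterns, for example in proteins implicated in misfolding
    diseases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
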