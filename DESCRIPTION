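Package: haplocall
Title: Mitochondrial Haplogroup Classification with Weighted Kulczynski Matching
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies mitochondrial DNA variant profiles into phylogenetic
    haplogroups. Loads decoupled tree packages (tree topology with
    haplogroup-defining variants, per-variant phylogenetic weights, hotspot
    exclusion lists, nomenclature rewrite rules, reference sequence and
    top-level cluster labels), reads sample profiles from hsd, VCF or FASTA
    input, runs pre-classification quality control on VCF batches, normalizes
    alignment-derived indels by right-alignment and rule rewriting, scores
    every haplogroup with a weighted Kulczynski (or Jaccard or Hamming) set
    similarity, assigns top-level clusters, and joins variant-level annotation
    tables onto the results. Includes a synthetic tree-package and
    sample-batch simulator so the full pipeline is testable without external
    downloads, plus a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
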