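Package: mangrovebarcodes
Title: Evaluation of DNA Barcode Markers for Plant Community Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for evaluating candidate DNA barcode
    markers in plant communities, motivated by mangrove floras where several
    plastid and nuclear markers (rbcL, ITS2, matK, trnH-psbA) compete as
    identification loci. Implements Kimura 2-parameter pairwise distances with
    pairwise deletion, barcode-gap analysis, Best Match and Best Close Match
    similarity identification, neighbor-joining bootstrap monophyly scoring,
    exhaustive multi-marker concatenation, Watterson's theta and nucleotide
    diversity per population, paired Wilcoxon signed-rank marker comparisons
    with common-language effect sizes, F1 hybrid diagnosis from heterozygous
    diagnostic sites, and infraspecific haplotype collapsing. A community
    simulator with ground-truth manifest generates realistic multi-marker,
    multi-population datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
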