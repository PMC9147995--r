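Package: coigap
Title: Threshold-Based Species Delimitation and Barcoding-Gap Analysis
    for COI Barcode Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intra- and interspecific variation in COI
    (cytochrome c oxidase subunit 1) barcode data and for threshold-based
    delimitation of molecular operational taxonomic units (MOTUs). Provides
    readers for BOLD-style specimen tables and FASTA files, a quality-filter
    cascade (identification level, ambiguous names, marker, minimum sample
    size, alignment gaps, internal stop codons, undefined distances, quantile
    outliers), Kimura two-parameter and p-distances with pairwise deletion,
    single-linkage threshold clustering, flexible threshold selection
    (density local minima, identification-error minimisation, minimum
    congeneric interspecific distance), congruence metrics against
    morphological species (match ratio; MATCH/SPLIT/MERGE/MIXTURE), and a
    calibrated simulator of BOLD-like insect barcode datasets with
    injectable data defects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
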