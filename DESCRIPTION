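Package: operonscape
Title: Gene-Neighborhood and Co-Occurrence Analysis of Prokaryotic Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genomic-context (synteny) analysis of prokaryotic gene
    families such as the [NiFe]-carbon monoxide dehydrogenases (CODH) and
    hybrid cluster proteins (HCP). Delineates the operon around each target
    gene from GFF3 annotations using an intergenic-distance chain rule,
    assigns functional categories to operon neighbors with prioritized,
    user-editable pattern rules over eggNOG-mapper and NCBI product
    annotations, computes assembly-level isoform counts and conditional
    co-occurrence probability matrices across clades and classes, and
    summarizes per-clade operon content with reporting cutoffs. Includes a
    deterministic synthetic-genome generator with known ground truth so the
    whole pipeline is testable without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
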