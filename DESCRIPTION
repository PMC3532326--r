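Package: jointvar
Title: Joint Effect Annotation of Co-Occurring Genomic Variants on
    Protein-Coding Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Database-independent annotation of the combined impact of
    co-occurring genomic variants (SNVs, insertions, deletions) on
    protein-coding transcripts. Compound VCF alleles are decomposed into
    atomic component variants, variants affecting the same transcript are
    evaluated jointly, and each variant x transcript pair receives a
    Sequence Ontology consequence (with Grantham-score classification of
    missense changes) while each transcript receives an open reading frame
    status (intact, preserved, disrupted, or fully deleted) together with
    reconstructed variant transcript and protein sequences. Also maps
    protein-domain coordinates to the genome and annotates variants with
    overlapping regions, and emits GVF, GFF, summary statistics, and
    Circos-compatible density tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
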