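Package: otupick
Title: Closed-Reference OTU Picking over a Concatenated Marker-Gene Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete closed-reference OTU-picking pipeline for amplicon
    (marker-gene) sequencing data. Reference marker genes are concatenated
    into a single artificial chromosome (a "concatesome") with an offset
    index mapping positions back to individual OTUs; reads are trimmed,
    deduplicated into a per-sample dictionary, optionally denoised by
    singleton/multiplicity filtering or by k-mer frequency profiling, and
    aligned under a percent-identity criterion either with the embedded
    FM-index aligner or by an external SAM-emitting aligner whose exact
    command line the package generates. Alignments are resolved back to OTU
    identities (junction-spanning hits are discarded), expanded to per-sample
    counts, and written as a taxonomy-annotated OTU table in sparse BIOM 1.0
    JSON or legacy tab-delimited format. A simulation module generates
    synthetic references, reads, and taxonomy maps with controlled error for
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
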