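Package: amplicall
Title: Primer-Anchored Variant Calling for Targeted Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidy pipeline for detecting SNPs and short indels in
    PCR-amplicon (targeted exon) paired-end sequencing data without a
    genome aligner. Read pairs are cleaned of capture-failure adapter
    sequence and sample-index bleed-through, collapsed into unique spliced
    sequences with occurrence counts, demultiplexed to amplicons via a
    minimal set of discriminating primer positions, aligned to their
    target with a band-restricted local-alignment recurrence, and called
    from per-position base frequencies. Includes a deterministic
    paired-end read simulator with SNP/indel spike-in and recall/TPR/FPR/
    accuracy evaluation against the simulated truth.
License: MIT
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
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
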