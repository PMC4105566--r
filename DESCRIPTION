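Package: unigeneqc
Title: Consistency-Based Quality Control and Gene Discovery for De Novo
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free evaluation of de novo transcriptome assemblies
    built from long single-end (454-style) reads, and the downstream
    gene-discovery bookkeeping that follows assembly selection. Implements
    adapter masking and largest-unmasked-substring read clipping, the
    Internal and External Consistency Indexes (ICI/ECI) that score how
    faithfully member reads map back to their contig consensus and how
    redundant pairs of contigs are, best-hit annotation summaries from
    tabular homology searches, interval-union subject coverage with a
    90-percent full-length gene rule, perfect microsatellite (SSR)
    detection with canonical motif grouping, and a deterministic synthetic
    read/assembly/hit-table generator used to validate every component
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
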