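Package: spongeid
Title: Multilocus DNA-Barcode Identification of Sponges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for multilocus DNA-barcode identification of sponges
    (phylum Porifera) from paired Sanger reads of the COI, 28S rRNA (D3-D5)
    and ITS loci. Provides windowed ambiguity trimming and validity filters
    for forward/reverse read pairs, IUPAC encoding of secondary peaks,
    deconvolution of length-variant heterozygotes into allele pairs,
    forward/reverse consensus building, a taxonomy-annotated reference
    database with exact local similarity search under Karlin-Altschul
    bit-score statistics, per-locus best-hit selection with a top-20 sanity
    scan, cross-locus arbitration by highest bit score, reconciliation with
    re-examined morphology under a 98 percent similarity rule, concordance
    summaries, and seeded simulators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
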