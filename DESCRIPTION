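Package: adaptrim
Title: Bit-Packed Adapter and Quality Trimming for Paired-End Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adapter and quality trimming for paired-end Illumina reads built
    on a 4-bit-packed DNA representation: a popcount-based 16-mer Hamming scan
    locates adapters and paired-end overlaps, quality-weighted scores and
    paired-read decision rules reconcile the candidate insert sizes, and
    overlap consensus calling corrects disagreeing base calls. Includes a
    sliding-window quality trimmer, auxiliary read filters, gzip-aware FASTQ
    input/output, a base-by-base read simulator with configurable
    substitution/insertion/deletion error profiles, and an evaluation toolkit
    (sensitivity, specificity, PPV, Matthews correlation) for benchmarking
    trimming accuracy against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
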