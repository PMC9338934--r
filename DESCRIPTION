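Package: strsift
Title: Alignment-Free Screening for Short Tandem Repeat Expansions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens short-read sequencing experiments for short tandem
    repeat (STR) expansions without alignment. Each read is scored by a
    DEFLATE compression ratio; reads below a read-length-dependent
    threshold are scanned for exact maximal repetitions, which are
    summarised into per-sample, per-motif information scores. Cohorts are
    then compared by a one-sided permutation Mann-Whitney motif screen
    with Benjamini-Hochberg correction, or by one-versus-many outlier
    detection against a BCa bootstrap bound on a background quantile. A
    simulation subsystem generates background reads, repeat-bearing
    reads, expansion loci and whole synthetic cohorts for threshold
    calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
SystemRequirements: zlib
NeedsCompilation: yes
Config/testthat/edition: 3
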