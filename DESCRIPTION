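Package: squiggleSTR
Title: Short Tandem Repeat Length Calling from Raw Nanopore Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Determines short tandem repeat (STR) allele lengths directly
    from raw nanopore current signals.  STR loci are described by simple
    repeat regular expressions (IUPAC symbols, optional blocks in braces,
    repeat groups in parentheses), compiled together with their flanking
    sequences into a k-mer finite-state automaton annotated with expected
    current levels from a pore model.  The normalized signal is aligned to
    the automaton by a constrained dynamic-time-warping dynamic program
    with minimum-dwell constraints, the repeat length is read off the
    warping path, and per-read estimates are summarized into a diploid
    genotype by outlier filtering and a Bayesian Gaussian mixture.  The
    package also provides spline-based signal polishing, adaptive
    event-size restriction driven by Welch's t statistic, derivation of
    gold-standard allele lengths from benchmark VCF-style records,
    evaluation metrics, and a squiggle simulator for download-free
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
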