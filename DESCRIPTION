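Package: ribodist
Title: Codon Decoding-Time Distributions from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of codon decoding-time distributions from ribosome
    profiling data. Normalizes per-gene footprint read-count (RC) profiles to
    normalized footprint counts (NFC), pools NFC samples per codon type,
    characterizes each codon's NFC distribution by maximum-likelihood fitting
    over thirteen candidate distribution families and by empirical features
    (mean, median, histogram mode, and the fitted log-normal mean, median and
    skewness), measures distances between NFC distributions (Jensen-Shannon,
    Hellinger, energy), tests per-codon distribution distinctness by repeated
    gene partitioning, detects the 5'/3' ORF regions with shifted NFC
    distributions via a sliding-window Wilcoxon scan, compares organisms by
    averaged codon-distribution distances with neighbor-joining clustering,
    and correlates NFC features with tRNA gene copy numbers and the tRNA
    adaptation index. Includes a continuous-time TASEP translation-elongation
    simulator (codon-specific dwell times, finite ribosome footprint,
    initiation control, traffic jams, sporadic pauses) used both to validate
    the distribution features and to generate synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
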