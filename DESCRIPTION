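Package: mafscan
Title: Motif Detection and Conservation Scoring in Multiple Alignment Format Files
Version: 0.1.0
Authors@R:
    person("mafscan", "developers", email = "mafscan@example.org", role = c("aut", "cre"))
Description: Searches the aligned blocks of UCSC Multiple Alignment Format (MAF)
    files for sequence motifs given as literal k-mers (matched with an
    Aho-Corasick automaton), JASPAR-format position weight matrices (scored as
    log-odds against a user background, with the hit threshold calibrated to a
    target p-value by sampling the background null), or regular expressions.
    Each hit is mapped between ungapped, gapped-column and forward-strand
    genomic coordinates, and its conservation across the other sequences of the
    block is summarised as a per-column similarity vector and a conservation
    percentage. Results are exported as BED, JSON and CSV. Includes a
    deterministic synthetic-MAF generator that plants motifs with prescribed
    edits so the whole pipeline can be validated against exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
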