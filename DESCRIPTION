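Package: avoidedwords
Title: Avoided Words and Minimal Absent Words in Biological Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects words that are statistically avoided in a sequence: words
    whose observed frequency falls short of the frequency expected from the
    counts of their longest proper prefix, suffix and infix. Both occurring and
    entirely absent avoided words are reported, the latter through minimal
    absent words. The implementation builds an annotated suffix tree with
    occurrence counts, word depths and suffix links, enumerates minimal absent
    words from it, and evaluates a chi-square-style deviation score for every
    candidate in time linear in the sequence length for a fixed alphabet.
    Includes brute-force reference implementations for validation, generators
    for synthetic and extremal test sequences, FASTA input/output, a
    command-line interface, and a utility for summarising self-complementary
    (restriction-site-like) words among the most avoided ones.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
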