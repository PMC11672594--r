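Package: pksdecode
Title: Decoding Type I cis-AT Polyketide Synthase Assembly Lines
Version: 0.1.0
Authors@R:
    person("pksdecode", "developers", email = "pksdecode@example.org",
           role = c("aut", "cre"))
Description: Motif-based annotation and decoding of type I cis-AT polyketide
    synthase (PKS) assembly lines. Locates KS, AT, DH, ER, KR, T and TE
    domains in assembly-line protein sequences, classifies acyltransferase
    substrate specificity (malonyl vs methylmalonyl), ketoreductase
    stereotypes (A/B1/B2), dehydratase activity and enoyl-isomerase
    candidacy from short active-site motifs, assembles module logic
    (including iterative "stuttering" and acyltransferase borrowing),
    predicts the polyketide backbone, macrolactone and hemiketal ring
    closure, tailoring chemistry and molecular formula, and provides
    monoisotopic mass, adduct m/z and heavy-oxygen exchange isotopologue
    arithmetic plus reaction free-energy profile bookkeeping. Ships a
    synthetic assembly-line generator with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
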