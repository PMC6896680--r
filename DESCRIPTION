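Package: cryptides
Title: In Silico Discovery of Bioactive Peptides and Cryptides in Peptidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening peptidomic data (LC-MS/MS peptide lists) for
    known bioactive peptides. Sample peptides are matched against a database
    of bioactive sequences in three modes: exact matches, partial matches
    (the sample peptide lies within a longer bioactive sequence), and
    cryptides (a short bioactive sequence is encrypted within a sample
    peptide). A rule-based simulation of gastric pepsin (pH > 2) proteolysis,
    with positional cleavage specificities, missed-cleavage and
    fragment-length constraints, predicts whether matched bioactives survive
    digestion or can be released from their parent peptides. Includes a
    bundled database of literature-reported bioactive peptides from a deer
    velvet antler peptidomic study, a seeded synthetic-peptidome generator
    with planted motifs for validation, and deterministic report writers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
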