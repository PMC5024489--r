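Package: cohortid
Title: Unique, Structured, Layered Study Identifiers for Epidemiologic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates guaranteed-unique, block-structured study identifiers for
    epidemiologic and clinical studies. Identifiers are assembled from ordered
    blocks (study center, study track, a unique random number, study visit and a
    check digit) and issued in disjoint layers: a personal-data ID (ID-P), a
    study-data ID (ID-S) and a temporary linkage ID (ID-T) drawn from disjoint
    thirds of the k-digit number range, plus external-partner IDs (ID-E) from a
    (k+1)-digit pool. Supports batch extension with uniqueness across batches,
    follow-up visit identifiers, new recruitment tracks, four check-digit
    algorithms (parity, weighted parity, a mod-11 Gumm-style scheme and the Damm
    quasigroup method), Code 128B barcode encoding, plain-text key-pair file
    output with audit logging, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    optparse,
    readr,
    tibble,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
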