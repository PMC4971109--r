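Package: pancub
Title: Pangenome Codon Usage Bias Analysis
Version: 0.1.0
Authors@R:
    person("pancub", "maintainers", email = "pancub@example.org", role = c("aut", "cre"))
Description: Stratifies bacterial pangenomes into presence classes
    (strain-specific through core gene families), quantifies per-gene codon
    usage bias with four measures (Nc, Nc-prime, CAI, CDC, plus RSCU), and
    diagnoses the relative contributions of mutation and selection per gene
    set via ENC-plots, neutrality-plot regression, correspondence analysis
    of RSCU, expression correlation, and tRNA-abundance similarity. Includes
    a seeded synthetic pangenome generator with known mutation/selection
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
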