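Package: ldiscan
Title: Mapping Long-Distance Intronic RNA Structure and Antisense Targets in
    SMN2 Intron 7
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing long-distance intra-intronic RNA duplexes by
    overlapping deletion and point-substitution scans, for modeling helix
    extension and loss under mutations, for quantifying and classifying SHAPE
    (1M7) chemical-probing reactivities from primer-extension lane intensities,
    and for rule-based prediction of antisense-oligonucleotide effects on
    alternative splicing. Ships a synthetic reconstruction of the SMN2 exon 7 /
    intron 7 substrate, the internal-stem (ISTL) structure model, and a seeded
    simulator for lane intensities and perturbation-scan phenotype tables so
    the whole inference chain is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
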