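Package: modrhod
Title: Annotation and Classification of Modular Microbial Rhodopsins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based annotation pipeline for modular microbial (type I)
    rhodopsins: transmembrane-topology validation by Kyte-Doolittle hydropathy
    segmentation, projection of reference key positions (bacteriorhodopsin,
    channelrhodopsin-2, proteorhodopsin and a canonical cyclase scheme) onto
    query sequences by global pairwise alignment, residue-fingerprint
    classification into channel-, pump-, sensory-type and non-retinylidene
    classes, spectral-tuning calls from the proteorhodopsin position-105
    polarity rule, cyclase-domain activity calls, position-conservation
    tabulation, and neighbor-joining phylogeny with bootstrap support.
    Includes a synthetic-sequence generator that plants known topology and
    residue fingerprints for end-to-end validation, and packaged residue
    tables for the curated modular-rhodopsin entries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
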