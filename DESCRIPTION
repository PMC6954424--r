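Package: halobarcode
Title: Molecule Counting and Interaction Calling for DNA-Barcoded Protein Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational pipeline for HaloTag-style protein barcoding
    experiments, in which each protein molecule carries a covalently linked
    oligonucleotide barcode composed of an 8-bp protein identifier, a 30-bp
    semi-random counting tag (24 random + 6 fixed bases) and two 31-bp
    amplification arms. Provides barcode schema definition and validation,
    FASTQ demultiplexing with fixed-base filtering, unique-molecule counting
    by edit-distance clustering of counting tags, sequencing-noise floors and
    positive/negative interaction calls (including Fisher's exact comparison
    of reference screens and immunoprecipitation dilution series), and a
    synthetic-read simulator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
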