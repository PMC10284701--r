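Package: suptrna
Title: Suppressor tRNA Design and Ribosome Readthrough Safety Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering suppressor tRNAs against premature
    termination codons and for assessing their molecular safety from
    ribosome profiling data. Designs anticodon-swapped tRNA variants with
    anticodon-stem and T-stem edit templates, scores eEF1A binding by
    additive per-pair free-energy contributions of the three T-stem base
    pairs, validates aminoacyl-tRNA-synthetase identity elements, and
    emits T7 in vitro transcription templates. Quantifies stop-codon
    readthrough from transcriptome-aligned ribosome footprints via
    stop-codon metagene profiles and the ribosome readthrough score
    (RRTS), and implements the small reporter, RT-qPCR delta-delta-Ct and
    microarray spike-in normalizations used alongside such screens. A
    synthetic-data module generates transcriptomes, footprint libraries
    with known readthrough rates, and assay tables so the whole pipeline
    runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
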