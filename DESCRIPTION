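Package: paleometh
Title: Simulation and Quality Control for Direct Methylation Detection in Ancient DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-simulates ancient DNA molecules carrying a bimodal
    vertebrate methylome through the laboratory treatments used for direct
    methylation sequencing of degraded samples (cytosine deamination damage
    with end bias, exonuclease VII overhang trimming, USER uracil excision,
    bisulfite and enzymatic methyl-seq conversion), then re-analyses the
    simulated reads with a three-letter bisulfite-aware aligner, a
    CpG/CHG/CHH methylation caller, library-complexity and spike-in control
    quality metrics, and a methylation-profile segmentation and beta-value
    comparison toolkit. Every analysis stage is testable against the
    simulator's ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
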