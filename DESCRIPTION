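Package: pixeltrim
Title: Predict 3' Truncation Positions for Amplicon Reads from FastQC Quality Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the 3'-end truncation position of 16S rRNA amplicon
    reads by computer-vision analysis of the FastQC per-base sequence
    quality plot: patch-based colour classification maps the raster to
    broad colour labels, bitmap digit recognition calibrates both axes,
    and a right-to-left scan at the quality-threshold row locates the
    pixel column where read quality falls below the threshold. Includes
    a numeric oracle operating on the fastqc_data.txt quality table, a
    FASTQ truncation tool, a synthetic FastQC-style report generator
    with pixel-level ground truth for verification, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    xml2,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
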