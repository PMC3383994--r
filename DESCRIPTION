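Package: ribofrag
Title: Ribonucleotide Frequency in Genomic DNA from Alkaline-Gel Densitometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the frequency of ribonucleotides covalently embedded in
    genomic DNA from alkaline (or enzymatic) fragmentation gels. Provides a
    forward simulator of lesion-bearing duplex genomes, ribonucleotide-specific
    cleavage agents (alkali, RNase H2, E. coli RNase HI, nicking endonucleases)
    and log-size gel electrophoresis with densitometry; the inverse analysis
    chain (background subtraction, ladder calibration, spline smoothing,
    transformation to nucleotide-coordinate fragment histograms, normalization
    to a fixed nucleotide total); and two frequency estimators: analytic
    fragment-count subtraction between mutant and control lanes, and a
    random-cut Monte-Carlo simulation fitted by hill climbing on the Manhattan
    distance between smoothed histograms. Includes nicking-endonuclease
    site-spacing statistics for calibrating the fragmentation scale, and
    per-cell arithmetic for genome-wide lesion burdens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
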