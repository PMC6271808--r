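Package: scotdiv
Title: Dominant-Marker Genetic Diversity Analysis for Band-Based Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of dominant molecular-marker data (SCoT, ISSR, RAPD and
    similar presence/absence band matrices) for germplasm collections:
    per-primer informativeness statistics (PIC, Shannon diversity, marker
    index, resolving power, genotype index), Nei-Li similarity with UPGMA
    clustering and bootstrap support, principal coordinate analysis, Mantel
    tests of isolation by distance, Shannon diversity partitioning within and
    between groups, dominant-marker AMOVA with Phi-PT permutation tests,
    closed-form G_ST partitioning from band frequencies, and post-processing
    of Bayesian admixture-clustering output (Evanno delta-K, membership
    thresholding). Includes a Balding-Nichols-style simulator of band
    matrices for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
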