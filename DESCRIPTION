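Package: hicamp
Title: Amplification Bias Analysis for Hi-C Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of amplification-free versus PCR-amplified
    Hi-C libraries: duplicate detection with wobble tolerance and PCR/optical
    classification, Lander-Waterman library-complexity estimation, Knight-Ruiz
    matrix balancing, distance-decay curves and decay-ratio comparison, GC
    representation tests, stratum-adjusted correlation (SCC), TAD border-strength
    index and border calling, A/B compartment eigenvectors, and aggregate peak
    analysis (P2LL, ZscoreLL). Includes a synthetic Hi-C library simulator with
    an explicit per-cycle PCR branching-process amplification model (GC- and
    distance-dependent efficiency) and optical-duplicate emulation, so every
    analysis stage can be validated against planted ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
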