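Package: FlySleepDI
Title: Drosophila Sleep Scoring and Cone-Restricted Sholl Defasciculation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for starvation-aligned sleep analysis of Drosophila
    Activity Monitor (DAM) beam-break records and for quantifying the
    spread of s-LNv dorsal axonal projections. Scores sleep as runs of
    inactivity, decomposes it into bout number and bout duration around
    the first light-dark transition after food deprivation, computes
    starvation-induced sleep loss with the group statistics used in fly
    sleep studies, and implements a cone-restricted Sholl
    defasciculation index (fraction of concentric-ring crossings of a
    traced arbor falling outside an optimally oriented narrow cone).
    Includes a synthetic-data generator (two-state semi-Markov
    sleep/wake chains and parametric arbors) with closed-form ground
    truth so the whole pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
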