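Package: situgrowth
Title: In Situ Bacterial Growth and Death Dynamics from
    Internal-Standard Normalized Amplicon Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates bacterial growth and death dynamics in soil from
    internal-standard normalized 16S rRNA gene amplicon time series.
    Implements exhaustive sliding-window log-linear regression with
    simulation-based false discovery rate calibration, k-means clustering
    of growth parameters into ruderal/competitive/scarcity-adapted
    life-history strategies, substrate-incorporation profile matching by
    pairwise sequence identity, and coupling of net community growth to
    CO2 mineralization through a net growth efficiency statistic.
    Includes a synthetic soil-microcosm simulator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
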