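Package: markddd
Title: Marked Point-Pattern Analysis of Distance-, Density- and
    Aggregation-Dependence in Tree Ecosystem Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying conspecific distance-, density- and
    aggregation-dependence (DDD) of per-tree ecosystem-service marks such as
    seed production and above-ground biomass, using marked point-pattern
    analysis on tree inventories organised in polygonal management units
    (concessions).  Implements four mark correlation functions (the
    nearest-neighbour mark mean, Schlather's mark correlation, a cumulative
    density correlation and a neighbourhood aggregation correlation based on
    the Clark-Evans index), mark-shuffling permutation null models with
    pointwise simulation envelopes, the boundary edge corrections the
    statistics require, diameter-based allometry, a plot-size scaling
    experiment comparing expected and measured per-hectare totals across
    raster resolutions, and a synthetic-data generator producing marked
    patterns with configurable DDD effects for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
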