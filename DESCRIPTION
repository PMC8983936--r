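Package: qwanat
Title: Quantitative Wood Anatomy of Tree-Ring Vessel Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative wood anatomy of diffuse-porous tree
    rings. Assigns individually measured xylem vessels to equal-width
    intra-ring sectors, applies sample-depth and sector-width filters, and
    computes hydraulic traits (mean and 95th-percentile vessel lumen area,
    hydraulically weighted mean diameter, Hagen-Poiseuille theoretical
    conductivity, vessel density, relative vessel area, vessel grouping
    index). Provides the two standardizations used in dendroanatomy:
    spline-ratio indexing with a cubic smoothing spline calibrated to a 50%
    frequency cutoff, and intra-ring profiles relative to the annual ring
    mean. Builds site chronologies with inter-series correlation (Rbar) and
    expressed population signal (EPS), runs Monte-Carlo permutation tests
    of independence with pairwise permutation t-tests and
    Benjamini-Hochberg correction, computes monthly Spearman climate
    correlations, classifies climatically extreme years, and ships a
    synthetic data generator emulating multi-site beech vessel data for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
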