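Package: isletnet
Title: Functional Connectivity Networks of Pancreatic Beta Cells from
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and characterizes functional connectivity networks of
    pancreatic beta cells from multicellular calcium fluorescence recordings.
    Provides trace preprocessing (photobleaching correction, F/F0
    normalization, response-based cell classification), Pearson-correlation
    network extraction with significance-based thresholds, graph-theoretic
    characterization (clustering, global efficiency, random-graph reference,
    small-world-ness, cumulative degree distributions and their power-law /
    exponential / truncated power-law fits), distance-resolved spatial
    analyses, sliding-window temporal analyses, and a multi-islet study
    pipeline with paired nonparametric regime statistics. Includes a
    synthetic islet generator that emulates glucose-driven calcium dynamics
    (activation and deactivation transients, plateau oscillations phase-lagged
    by traveling calcium waves, photobleaching drift and imaging noise) so the
    whole pipeline can be exercised end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
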