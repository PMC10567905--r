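Package: crownfit
Title: Digital Marginal and Internal Fit Metrology for Crown Restorations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the marginal and internal fit of crown-shaped dental
    restorations from triangle surface meshes. Reads and writes STL (binary
    and ASCII) and colour PLY meshes, orders annotated margin landmarks into
    closed margin curves, performs reference best-fit rigid alignment via
    trimmed iterative closest point registration, measures the absolute
    marginal discrepancy as the Hausdorff distance between margin curves,
    samples the intaglio surface with dart-throwing Poisson-disk sampling and
    computes internal gap-distance fields with histogram and colour-map
    outputs, and compares cohorts with pooled two-sample t tests computed
    from raw per-crown metrics or from printed summary statistics. A
    synthetic abutment/crown generator with analytic ground truth supports
    end-to-end validation without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
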