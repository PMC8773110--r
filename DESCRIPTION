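Package: corrfront
Title: Moving-Boundary Analysis of Corrosion-Triggered Delamination at
    Metal-Polymer Interfaces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and measures corrosion-driven interface diffusion and
    delamination in encapsulated implantable devices. Implements a
    Stefan-type moving-boundary model of interface diffusion with a
    Goodman heat-balance-integral closed form (front position X = alpha
    sqrt(t)) and an explicit finite-difference solver with auditable mass
    balance; an image-analysis stage that thresholds time-lapse frames of
    a corroding droplet specimen, counts pixels and extracts the corrosion
    front trace; a tilted-plate cuvette analysis yielding bulk
    diffusivities via the Einstein-Smoluchowski relation with lag-time
    handling; three-phase segmentation of front traces (sqrt-t, linear,
    artifact jump) with a constant-lag delamination front and an
    interface/bulk merge-time predictor; and a synthetic-data generator
    that forward-simulates both experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
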