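Package: bomap
Title: Border-Ownership Maps and Functional Minimization for Figure-Ground
    Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects real and illusory object boundaries in small synthetic
    gray-scale images by minimizing a cost functional over a border-ownership
    map, a tensor assigning signed boundary-strength values to every pixel and
    discrete direction. The functional combines alignment with image edges,
    boundary-strength limiting, suppression away from edges, one-sidedness of
    ownership, boundary continuity, and a convexity-weighted bending penalty.
    Multiple image interpretations are enumerated as distinct local minima
    found with repulsive particles under a coarse-to-fine graduated
    relaxation, ranked by cost, and the top-most object shape is recovered by
    level-set contour evolution with a border-ownership friction term.
    Includes a stimulus generator (step edge, square, C-shape, Kanizsa
    pacman figures at parametric support ratio) and PGM/PNG raster input
    and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
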