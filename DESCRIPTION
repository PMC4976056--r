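Package: osteopair
Title: Pair-Matching of Bilateral Skeletal Elements by Mesh-to-Mesh Value
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sorts commingled skeletal remains by pair-matching left and right
    antimeres from 3D surface meshes.  One side is mirror-imaged, every
    left-right candidate pair is rigidly registered with a two-stage iterative
    closest point procedure (multi-start subsampled point-to-point rough
    alignment, then full-sampling point-to-plane fine alignment with normal
    compatibility), and each registration is summarised as a single
    mesh-to-mesh value in millimetres.  Pairs are declared by a mutual
    best-match rule over the left-by-right comparison matrix and scored
    against known pairings with per-bone sensitivity and specificity.
    Includes OBJ/STL/PLY mesh input and output, deviation-band maps, a
    mean + 2 SD threshold analysis, and a seeded generator of synthetic
    long-bone populations with controlled bilateral asymmetry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
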