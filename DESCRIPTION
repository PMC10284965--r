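Package: palatoplate
Title: Automated Design of Presurgical Orthopedic Plates from Cleft
    Palate Surface Scans
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes 3D-printable presurgical orthopedic plates for
    unilateral and bilateral cleft lip and palate from triangle-mesh
    surface scans of the neonatal palate. Provides landmark detection via
    per-vertex proximity maps with a two-stage coarse-to-fine predictor
    and weighted Procrustes alignment, region-staged nonrigid iterative
    closest point registration of labeled palate templates with alveolar
    cleft bridging, constrained sphere-based cleft filling,
    curvature-selective Laplacian smoothing, surface offsetting, and
    watertight volumization with fit diagnostics. Includes a synthetic
    neonatal palate generator with ground-truth landmarks and region
    labels so the full pipeline can be exercised and validated without
    patient data, plus OBJ/PLY/STL mesh input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
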