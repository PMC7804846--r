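Package: catsflow
Title: Computational Fluid Dynamics of the Prostatic Urethra After Transurethral Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds idealized two-dimensional models of the post-transurethral-surgery
    lower urinary tract (bladder, hollowed prostatic urethra, distal urethra), meshes
    them with triangle elements, solves steady pressure-driven incompressible flow with
    a finite-volume SIMPLEC solver (laminar or k-epsilon RANS closure with wall
    functions), and extracts urodynamic observables: recirculation ("vortex") presence
    and diameters via the streamfunction separatrix, the midpoint velocity of the
    external urethral orifice, and the prostatic-urethra diameter ratios RPU-1 and
    RPU-2. Includes a 210-case parametric amplification array, cohort summaries with
    Mann-Whitney tests and regressions, grid-independence checks, and CSV/MSH/VTK
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
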