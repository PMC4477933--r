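Package: mvrepair
Title: Virtual Mitral Valve Repair Simulation: Quadrangular Resection,
    Ring Annuloplasty and Dynamic Finite-Element Valve Closure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for personalized mitral-valve repair
    simulation. Builds labeled synthetic prolapsed-valve models (a seeded
    parametric stand-in for 3D transesophageal-echo derived geometry),
    performs virtual quadrangular posterior-leaflet resection with spline
    suture-curve plication and annuloplasty ring sizing and implantation,
    runs an explicit dynamic finite-element simulation of valve closure
    (Fung-type anisotropic hyperelastic membrane leaflets, tension-only
    Ogden cable chordae, penalty contact with Coulomb friction, prescribed
    annular motion and transvalvular pressure), and quantifies leaflet and
    chordal stresses, coaptation lengths and annular dimensions before and
    after repair.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
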