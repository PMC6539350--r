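Package: mvelastica
Title: Elastica-Based Biomechanics of Mitral Valve Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Planar biomechanical model of the mitral valve for planning
    restrictive annuloplasty combined with papillary muscle approximation in
    ischemic mitral regurgitation. Each leaflet is an inextensible Euler
    elastica under an inclined end-point load, solved in closed form with
    incomplete elliptic integrals; chordae tendineae are one-dimensional
    Fung-type hyperelastic elements anchored on movable papillary muscles.
    The package identifies the preoperative configuration from
    echocardiographic measurements by a seeded random search, predicts the
    postoperative configuration under three surgical scenarios (optimized
    annuloplasty plus papillary approximation, annuloplasty alone, and
    complete approximation to a prescribed interpapillary distance), and
    reports non-dimensional effectiveness indicators (root bending-moment,
    chordal stress and stretch ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
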