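Package: namplate
Title: Semi-Automated Design of Intraoral Molding Plates for Unilateral
    Cleft Lip and Palate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates series of presurgical nasoalveolar molding (NAM)
    plates for newborns with unilateral cleft lip and palate from a single
    digitized maxillary cast. Provides triangle-mesh input/output and
    validation (STL/OBJ), a parametric synthetic neonatal cleft-maxilla
    generator with known ground truth, automatic alveolar-crest detection
    with direct least-squares ellipse fitting, ellipse-guided virtual cleft
    bridging, shell-offset plate construction with retention pin and
    ventilation hole, growth-model-driven plate series planning, and
    landmark-based morphometrics with exact Wilcoxon tests by enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
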