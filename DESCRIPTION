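Package: uaeopt
Title: Response-Surface Optimization of Ultrasound-Assisted Polyphenol
    Extraction with Metabolite Mass Annotation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing ultrasound-assisted extraction of plant
    polyphenols by designed experiments. Constructs three-factor Box-Behnken
    designs with replicated center points, fits second-order response-surface
    models on coded factors with a full ANOVA panel (lack of fit, pure error,
    PRESS-based predicted R-squared, adequate precision), and locates joint
    optima of several responses by Derringer desirability maximization. A
    small multilayer-perceptron regressor trained by Levenberg-Marquardt or
    BFGS provides the customary neural-network comparison, with RMSE, AAD and
    SEP comparison metrics and RSD/RSE optimum validation. A companion
    annotation toolkit parses elemental formulas, computes monoisotopic
    deprotonated-adduct m/z values, matches peak lists against a compound
    library by ppm error and flags diagnostic neutral losses. Seeded
    generators simulate quadratic response surfaces, mass peak lists and
    dose-response curves so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
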