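Package: nutgeom
Title: Nutritional Geometry of Ant-Colony Feeding Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for colony-level nutritional-geometry analyses of
    laboratory feeding experiments with ants. Implements two-dimensional
    protein:carbohydrate intake-target estimation and rule-of-compromise
    classification from choice and no-choice assays, mass-balance intake
    accounting from daily diet-cube weighings with evaporation controls,
    second-degree response-surface models on the protein:carbohydrate:lipid
    simplex (right-angled mixture triangle) with lack-of-fit testing and
    constrained maximization, thin-plate-spline nutritional landscapes with
    fundamental-macronutrient-niche delineation, the associated treatment
    statistics (one-way ANOVA with Tukey letters, paired t-tests, binomial
    mixed models of worker survival), and a synthetic colony-foraging data
    generator with known ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
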