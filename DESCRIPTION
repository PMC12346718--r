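Package: rumenferm
Title: In Vitro Rumen Fermentation Kinetics, Methane Partitioning and
    Nutritive Value of Forages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for in vitro gas-production studies of ruminant feeds:
    blank correction and organic-matter normalization of cumulative gas
    curves, fitting of the three-parameter sigmoidal (Groot-type) kinetic
    model with closed-form maximum fermentation rate (Rmax) and its time
    (Tmax), stoichiometric partitioning of fermentation gas into carbon
    dioxide and methane from volatile fatty acid end-point profiles,
    nutritive-value equations (non-structural carbohydrates, Menke-Steingass
    metabolizable energy, organic-matter degradability), and the factorial
    statistical layer typical of such studies (Shapiro-Wilk screening,
    one-way and two-way ANOVA with Tukey HSD compact letter displays and
    SEM). A synthetic-study generator with known ground truth emulates
    bottle-level designs for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    minpack.lm,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
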