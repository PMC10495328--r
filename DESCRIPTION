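Package: orthosetup
Title: Three-Dimensional Evaluation of Virtual Orthodontic Setups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of virtual orthodontic setup models built
    from CBCT-derived roots and intraoral-scan crowns. Computes signed
    mesiodistal angulation and buccolingual inclination of each tooth from
    mesial/distal/apex landmark triplets via tooth-specific projection planes
    against a shared occlusal reference plane, derives adjacent-tooth root
    parallelism summaries, measures root exposure (dehiscence and fenestration)
    from watertight tooth and trimmed alveolar-bone meshes against per-tooth
    alveolar-crest reference discs, and compares setup conditions with the
    associated repeated-measures statistics (intraclass correlation,
    repeated-measures ANOVA with Mauchly's sphericity test and Bonferroni
    post-hocs, Friedman with Wilcoxon signed-rank post-hocs, and McNemar
    tests). Includes a seeded synthetic dental-arch generator with analytic
    ground truth for validation and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
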