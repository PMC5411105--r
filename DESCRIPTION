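Package: weanmix
Title: Weaning Reconstruction from Bone-Collagen Stable Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs breastfeeding and weaning practices from bone-collagen
    carbon and nitrogen stable-isotope measurements of juvenile and adult-female
    skeletal series. Provides collagen quality screening and age grouping, a
    keratin-based offset chain that infers the breast-milk isotope source from
    maternal collagen, a concentration-dependent Bayesian mixing model for
    dietary source proportions by age group, an approximate Bayesian computation
    model of weaning start and end ages with age-dependent collagen turnover,
    group comparison statistics, and synthetic-cohort generators for
    ground-truth testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
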