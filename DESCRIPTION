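Package: afcea
Title: Cost-Effectiveness Modelling of Catheter Ablation versus
    Antiarrhythmic Drugs for Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A decision-tree plus Markov cohort model comparing catheter
    ablation with antiarrhythmic drug therapy (amiodarone) for rhythm
    control of paroxysmal atrial fibrillation, from the perspective of a
    publicly funded health care system. Provides DerSimonian-Laird
    random-effects pooling of trial proportions, derived-parameter
    calculators (probability rescaling, relative-risk application),
    deterministic cost-effectiveness analysis with incremental
    cost-effectiveness ratios, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a one-way sensitivity
    analysis grid. External inputs that are not published (life tables,
    age- and sex-specific event mortality, population utilities) are
    emulated by deterministic synthetic fixtures that can be swapped for
    real tables via delimited files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
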