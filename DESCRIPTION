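Package: peepicp
Title: PEEP Titration Effects on Intracranial Pressure and Cerebrovascular
    Reactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multimodal physiological recordings from
    PEEP (positive end-expiratory pressure) titration experiments with
    intracranial monitoring, built around a synthetic physiology simulator
    with known ground truth. Provides waveform cleaning and threshold
    artifact rejection, 0.1 Hz coarse-graining, cerebrovascular reactivity
    (PRx) and compensatory reserve (RAP) indices from moving Pearson
    correlations, esophageal-balloon respiratory mechanics (occlusion
    detection, transpulmonary pressures, elastance partitioning, driving
    pressure, mechanical power), per-period aggregation, and the randomized
    crossover statistical analysis (normality routing, crossover assumption
    checks via linear mixed-effects models, PEEP-by-position ANOVA with
    Welch/Kruskal fallbacks, and baseline-covariate models of the ICP
    response).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
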