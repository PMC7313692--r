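Package: cpreeg
Title: Quantitative EEG and Carotid Blood Flow Recovery During CPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-channel frontal EEG during
    cardiopulmonary resuscitation in a ventricular-fibrillation cardiac
    arrest model. Generates cohorts of coupled EEG and hemodynamic
    recordings following a witnessed out-of-hospital arrest timeline,
    extracts the ~3-s pre-defibrillation pause epochs, computes eleven
    quantitative EEG parameters (peak magnitude, bispectral SynchFastSlow,
    spectral band-power ratios, log energy entropy and Renyi entropy)
    under a three-sub-epoch averaging scheme, and relates them to the
    per-epoch carotid blood flow recovery rate via Pearson correlation,
    quartile-group one-way ANOVA with Dunnett T3 post hoc comparisons,
    and ROC analysis with Youden-index cut-offs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
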