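Package: sleepdbs
Title: Cortico-Basal Sleep Analysis for Sensing-Enabled Deep Brain Stimulation Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for multi-night intracranial field-potential
    recordings (cortical ECoG plus subcortical DBS leads) paired with portable
    polysomnography. Provides artifact-robust preprocessing (accelerometry-based
    stream synchronization, spike excision, hybrid seeded/adaptive ECG template
    subtraction with a Woody filter), epoch-wise Welch band power and
    cortico-subcortical magnitude-squared coherence, NREM beta-delta coupling
    and lead-lag estimation, transition-locked Hilbert envelope dynamics around
    spontaneous awakenings, linear mixed-effects inference with a parametric
    bootstrap likelihood-ratio comparison, and rapid NREM-versus-wake SVM
    classification from band-power features. A synthetic-night generator with
    queryable ground truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
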