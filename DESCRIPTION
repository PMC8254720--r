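Package: pupilcontext
Title: Trial-Level Pupillometry of Contextual Size Illusions
Version: 0.1.0
Authors@R: person("Pupilcontext", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for trial-level analysis of pupillary light
    responses to stimuli embedded in a 3D size-illusion (Ponzo / Emmert's-law)
    context, and their relation to autistic traits measured with the
    Autism-Spectrum Quotient (AQ). Implements eye-tracker trace cleaning
    (gross and velocity-based artifact rejection, 10 Hz down-sampling,
    baseline correction, missing-data gating), per-trial response
    summarisation, linear mixed models with participant random intercepts,
    Pearson and partial correlations with JZS Bayes factors, median-split
    analyses, and a synthetic-session generator that emulates 500 Hz pupil
    traces whose light-response amplitude follows perceived rather than
    physical stimulus size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
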