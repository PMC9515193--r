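Package: dietconn
Title: Diet Moderation of Internetwork Resting-State Connectivity Effects on Cognition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores Mediterranean-diet (MeDi) adherence from food-frequency
    questionnaire category intakes, reduces ROI-level resting-state fMRI time
    series to Fisher-z internetwork connectivity summaries (framewise
    displacement, scrubbing, band-pass filtering, nuisance regression,
    distance exclusion, positive-only averaging), assembles an analytic cohort
    through a sequential exclusion cascade, and fits the moderation model
    family testing whether diet-adherence group changes the association
    between internetwork connectivity and reference-ability cognitive
    composites. Includes a synthetic cohort generator with planted,
    recoverable effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
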