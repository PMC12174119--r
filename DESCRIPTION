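Package: graphomarker
Title: Writing-Process Digital Biomarkers for Cognitive Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts kinematic digital biomarkers from timestamped
    touch-screen handwriting sessions in which a subject writes the Chinese
    character for "rice" (mi) ten times, and runs the associated cohort
    screening pipeline for mild cognitive impairment. Sessions are segmented
    into strokes and pauses; ten information-processing-speed biomarkers
    (pause and timing features) and eleven executive-function biomarkers
    (stroke count, trajectory length, speed and task-score features) are
    computed per session. Cohort tools include a normality-routed
    differential battery (independent t-test or Mann-Whitney U),
    likelihood-ratio stepwise logistic biomarker selection, ROC/AUC with
    DeLong confidence intervals, and a priori two-sample t-test sample-size
    computation. A seeded synthetic-session generator, calibrated to
    published group summaries, makes the whole pipeline testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
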