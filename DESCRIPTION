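Package: hglock
Title: Stimulus- and Behavior-Locked High-Gamma Activity in Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event-related intracranial EEG recordings
    that separates stimulus-locked from behavior-locked high-gamma (70-150 Hz)
    activity. Computes single-trial high-gamma event-related band power (ERBP)
    via zero-phase FIR filtering, Hilbert envelope extraction, log transform
    and prestimulus baseline normalization; classifies recording sites into
    stimulus-related, behavior-related, intermediate, or unresponsive patterns
    by one-tailed t-tests in post-stimulus and pre-response windows; aggregates
    site labels into regional prevalence tables, hemispheric Fisher-exact
    asymmetries with Benjamini-Hochberg correction and stimulus/behavior
    balance indices; relates single-trial power to reaction times by Spearman
    correlation with region-level Wilcoxon tests; and averages region-level
    ERBP envelopes. A ground-truthed synthetic generator emulates the
    target-detection trial structure (Gaussian inter-stimulus intervals,
    lognormal reaction times, band-limited bursts locked to stimulus or button
    press, 1/f background, artifacts) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
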