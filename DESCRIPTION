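Package: pinchbind
Title: Action-Effect Binding Analysis for Pinch-Force Prime-Probe Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for prime-probe experiments that
    test whether task-irrelevant pinch parameters (peak force, force integral,
    duration) are bound to, and retrieved by, auditory action effects. Provides
    a synthetic session generator with a controllable retrieval strength,
    force-trace event detection with a threshold-plus-persistence rule, the
    multi-stage trial screening cascade, and the similarity statistics:
    Fisher-Z prime-probe correlations, mean absolute differences, paired
    t-tests with Cohen's dz, JZS Bayes factors, a noncentral-t power solver,
    and the 2x2 mixed ANOVA with generalized eta squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
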