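Package: knowtrace
Title: Knowledge Tracing and Adaptive Tutoring for Dyscalculia Intervention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An adaptive-learning engine for arithmetic intervention in
    children with dyscalculia. Provides a prerequisite skill graph (DAG) over
    arithmetic skills with JSON and DAGitty-text serialization, a dynamic
    Bayesian network student model that traces per-skill mastery from
    observed responses with a bounded five-step memory, a rule-based
    pedagogical controller that adapts task selection (stay, advance,
    remediate) with self-tuning posterior thresholds, executable buggy rules
    that diagnose wrong answers into five characteristic dyscalculia error
    cases, a simulated-learner harness for end-to-end evaluation without
    real student data, and assessment analytics (per-skill dispersion,
    speed-accuracy correlation, Welch's heteroscedastic ANOVA, and a-priori
    power analysis for the paired t test via the noncentral t distribution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
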