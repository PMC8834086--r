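Package: goalrec
Title: Goal Recognition from Partial 2D Motion Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes the goal of an observed agent moving in the plane from
    incrementally revealed trajectory prefixes. Implements four published
    rationality-based goal recognizers (Ramirez-Geffner cost-difference,
    mirroring cost-ratio, Masters-Sardina last-observation sigmoid, and the
    Dragan legibility posterior), an idealized plan-library matcher, and a
    library-based rational goal recognizer (LRGR) that scores detours through
    the closest known plan and falls back to pure rationality when no plan is
    close. Includes a parametric generator for two-goal reaching scenarios with
    curvature-ranked plan libraries, an incremental-observation evaluation
    harness with a decision-convergence metric, leave-one-out and library-size
    robustness experiments, and simple regression utilities for comparing
    convergence points with response-time data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
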