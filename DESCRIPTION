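Package: standshift
Title: Simulation and Analysis of FES-Assisted Weight-Shift Standing Exercise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for generating, recording and analysing side-to-side
    weight-shift standing exercise sessions driven by cyclic functional
    electrical stimulation (FES). Provides the cyclic two-group stimulation
    envelope and pulse-train generator, load-cell and force-plate calibration
    models, a synchronized multi-stream session container, a seeded
    virtual-participant simulator that produces physically consistent
    ground-reaction, arm-rail and clavicle-marker recordings, a rendering-free
    skiing exergame feedback model, ground-reaction-force cycle segmentation
    with body-weight normalisation and range-of-motion estimation, and
    repeated-measures ANOVA with Tukey post-hoc comparisons over session
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
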