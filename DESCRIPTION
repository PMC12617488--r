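Package: corridorcode
Title: Spatial and Context-Selective CA1 Population Codes in a Virtual
    Go/No-Go Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for calcium-imaging recordings of hippocampal
    CA1 populations in a virtual contextual go/no-go task: behavioral scoring
    of rewarded/unrewarded corridor laps and lick/speed selectivity indices,
    per-corridor place-cell rate maps with spatial reliability, tuning
    specificity and Skaggs information, circular-shift shuffle significance
    with Holm-Bonferroni correction, corridor- and zone-selectivity
    statistics, population-vector and lap-to-lap correlation analyses around
    context-switch and reward-reversal events, naive-Bayes decoding of
    position and corridor identity, trace-correlation ROI matching, and a
    synthetic session generator with ground-truth labels for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
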