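Package: voltfinger
Title: Tissue Fingerprinting from Differential Pulse Voltammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrochemical tissue fingerprinting based
    on the Brdicka reaction. Simulates labelled differential pulse
    voltammograms with tissue-, subject- and replicate-level structure,
    detects and names local extremes by discrete differentiation, derives
    Haar-wavelet step attributes of the curves, classifies tissue of origin
    with decision trees under stratified 10-fold cross-validation, and
    characterizes the near-linear segment between the Cat2 minimum and the
    last maximum by inflection-anchored line fits whose per-tissue families
    share a common intersection point. Includes RadViz projection of selected
    wavelet attributes and text-format readers and writers for curve and
    feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rpart,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
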