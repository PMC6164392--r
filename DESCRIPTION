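Package: lumitox
Title: Mixture Toxicity Prediction for Bacterial Bioluminescence Inhibition Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dose-response analysis and mixture-toxicity prediction for
    whole-cell Aliivibrio fischeri bioluminescence inhibition assays, as used
    for early-warning water-quality monitoring in recirculating aquaculture
    systems. Fits four-parameter log-logistic (logit) dose-response curves to
    control-normalised luminescence inhibition, inverts them to effect
    concentrations (ECx), predicts mixture toxicity under concentration
    addition (CA) and independent action (IA), linearises both into LCA/LIA
    regression models, and evaluates predictions with the model deviation
    ratio (MDR), relative deviations and additive/synergistic/antagonistic
    behaviour classification. Includes uniform-design ray planning for
    fixed-ratio mixture experiments, recommended water-quality limit checks
    for Atlantic salmon farming, CSV readers and writers for plate, curve and
    ray tables, and a synthetic plate-data generator with configurable
    mixture interaction for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
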