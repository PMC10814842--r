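Package: resrisk
Title: Pesticide Residue Dissipation Kinetics and Dietary Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A residue-to-risk pipeline for supervised pesticide field trials:
    analytical method-validation statistics (linear calibration, recovery,
    relative standard deviation, matrix effect, limit-of-quantification
    screening), first-order dissipation kinetics with half-life estimation,
    deterministic acute (NESTI, percent of the acute reference dose) and
    chronic (estimated daily intake, percent of the acceptable daily intake)
    dietary-risk equations, and a probabilistic Monte-Carlo exposure model
    with lognormal fitting of consumption and residue data. Includes a
    synthetic-data generator with known ground truth for first-order decay,
    spike-recovery tables and subgroup consumption samples, so the whole
    chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
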