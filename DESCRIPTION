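Package: virtualarm
Title: Virtual Control Arms for Single-Arm Post-Prostatectomy Adjuvant Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs "virtual" (nomogram-derived) control arms for single-arm
    adjuvant-therapy trials after radical prostatectomy. Per-patient
    progression-free-survival probabilities at fixed years after surgery are
    fitted with a monotone curve and inverted to the time at which survival
    probability falls to a threshold q; eight thresholds (q = 0.60 to 0.95 by
    0.05) define eight conversion models of increasing stringency. Reference
    case sets trained by a prefix scan that minimises the observed-versus-virtual
    logrank chi-square tell which model fits which kind of cohort; the model for
    a new trial cohort is selected by weighted Euclidean distance on eight
    clinical variables; the treated cohort's observed survival is then compared
    with its own virtual control arm by the logrank test. Includes a synthetic
    cohort generator (proportional-hazards Weibull with controllable nomogram
    miscalibration) so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
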