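Package: grmcat
Title: Graded Response Model Calibration, Assumption Checks, and Post-Hoc
    Computerized Adaptive Testing Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychometric validation toolkit for polytomous item banks on the
    PROMIS T-score metric. Implements Samejima's graded response model
    (category probabilities, Fisher information, EAP scoring, Bock-Aitkin
    marginal maximum likelihood calibration, Orlando-Thissen S-X2 item fit),
    item-response-theory assumption checks (polychoric correlations, KMO,
    parallel analysis, ordinal factor analysis, Mokken scalability),
    differential item functioning by ordinal logistic regression with the
    McFadden pseudo-R2 change criterion, Stocking-Lord test characteristic
    curve linking, and post-hoc computerized adaptive testing simulation with
    maximum Fisher information item selection and a standard-error stopping
    rule. Ships calibrated anxiety and depressive-symptoms pediatric item
    banks as fixtures and a synthetic-cohort generator for fully reproducible
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
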