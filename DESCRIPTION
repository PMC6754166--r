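Package: ovcsim
Title: Microsimulation of Chemotherapy Implementation Strategies in
    Advanced Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Decision-analytic microsimulation of post-operative
    chemotherapy strategies for stage IIIC epithelial ovarian cancer. A
    monthly-cycle survival engine applies proportional-hazards adjustments,
    a 12-year cure assumption and lifetable background mortality to a
    mixture-cure Weibull baseline; a decision tree assigns regimens
    (standard IV, intraperitoneal+IV, bevacizumab+IV, HIPEC+IV, dose-dense)
    by surgical triage and cytoreduction status. Includes a deterministic
    cohort solver, a seeded individual-level Monte Carlo simulator, a
    calibration stage that recovers unpublished survival inputs from
    published life-expectancy and median-survival results, one-way
    sensitivity and imperfect-implementation analyses, and synthetic
    lifetable and registry-extract generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
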