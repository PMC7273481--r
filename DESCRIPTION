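Package: ihcmine
Title: Rule-Based Mining of Hormone Receptor Results from Pathology Reports
Version: 0.1.0
Authors@R:
    person("Pathology", "Informatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A phrase-matching pipeline that detects regional and distant
    metastatic breast cancer cases in free-text pathology reports, extracts
    estrogen receptor (ER), progesterone receptor (PR) and HER2
    immunohistochemistry results written in the 2013 CAP reporting
    conventions, records them to CSV, scores detection and extraction
    against gold annotations, and compares receptor expression between
    metastatic site groups with Pearson chi-squared tests (Yates-corrected
    for 2x2 tables). Includes a seeded synthetic-corpus generator with
    ground truth so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
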