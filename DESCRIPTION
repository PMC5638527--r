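Package: ppct
Title: Peripapillary Choroidal Thickness Morphometry and Sector Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying local peripapillary choroidal thickness (ppCT)
    from circumpapillary OCT circle scans, optic disc tilt by sine-curve fitting of
    the retinal pigment epithelium trajectory, and the papillo-macular position
    (PMP) angle from fundus landmarks. Includes the accompanying statistical
    battery (Spearman rank correlation, standardized multiple regression,
    Steel-Dwass all-pairs comparison, Mann-Whitney U, Fisher-z comparison of
    correlations), a seedable synthetic cohort and boundary-trace generator with
    calibrated effect structure, and an end-to-end study pipeline with eligibility
    filtering, subgroup analyses and report output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    readr,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse,
    yaml
Config/testthat/edition: 3
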