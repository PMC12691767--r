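Package: ltcasim
Title: Dynamic Microsimulation of Long-Term-Care Allowance Demand
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Projects demand for and public expenditure on a cash-for-care
    benefit scheme with seven need-graded allowance levels (modelled on the
    Austrian Pflegegeld) for the population aged 65 and older.  Provides a
    seeded synthetic-data generator for survey microdata and aggregate
    benefit statistics, a two-step logistic prevalence model (any-receipt
    and severity) whose education differentials are aligned to aggregate
    level prevalences by non-linear root finding, a monthly dynamic
    microsimulation engine with mortality alignment, cohort entry and
    compression-of-morbidity scenarios, and accounting routines for annual
    expenditure, lifetime benefit costs by sex and education, and
    age-specific prevalence reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
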