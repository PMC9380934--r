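Package: abacea
Title: Cost-Effectiveness Model of Early Intensive Behavioural Intervention for Autism
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A monthly-cycle cohort decision model comparing early intensive
    applied-behaviour-analysis (ABA) based interventions with treatment as
    usual for pre-school autistic children, from UK health/social-care and
    public-sector perspectives. Cohort mean cognitive ability (IQ) and
    adaptive behaviour (VABS) scores drive education placement (ordered
    logit), utility (QALYs), and social/medical cost regressions over a
    15.5-year horizon with half-cycle corrected 3.5 percent discounting.
    Includes scenario analyses (lifetime adult-independence phase with a
    simulated-IPD ordered-logit fit; observed education placement), one-way
    deterministic sensitivity analysis (tornado), probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and
    synthetic-data generators for life tables and adult individual-level
    records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
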