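Package: srsminer
Title: Spontaneous-Report Filtering, Descriptive Comparison and
    Disproportionality Signal Mining for Anticancer-Drug ADRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spontaneous reporting system (SRS) databases
    of adverse drug reaction (ADR) reports, oriented to comparing monoclonal
    antibody (mAb) with traditional anticancer drugs. Provides report-level
    inclusion/exclusion filtering with an auditable exclusion log, the
    standard variable codings (polypharmacy, serious-ADR, impact dichotomy,
    onset-time bins), descriptive crosstabulations with chi-square or Fisher
    exact tests, binary logistic regression for ADR severity and impact,
    Mantel-Haenszel stratified odds ratios, and drug-event-combination signal
    mining by reporting odds ratio (ROR), proportional reporting ratio (PRR)
    and the MHRA criterion (Yates-corrected chi-square). Includes a seeded
    synthetic-SRS generator with planted drug-event signals and a
    deterministic reference dataset reproducing published marginal counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
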