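Package: wellcost
Title: Cost-Consequence Modelling of Workplace Mental Wellbeing
    Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic cost-consequence model for workplace mental
    wellbeing interventions, evaluated from the employer perspective over
    a one-year horizon. Computes per-component incremental costs
    (absenteeism, presenteeism, staff turnover, intervention), the total
    incremental cost and the net cost per participating employee, with
    savings reported as negative incremental costs. Provides one-way
    deterministic sensitivity analysis with tornado ordering, closed-form
    break-even (threshold) analysis over the affine model, consumer price
    index adjustment of unit costs between price years, strict reading
    and writing of scenario configuration files (YAML or JSON), rounded
    report tables, and a command-line interface. Six hypothetical case
    studies ship as bundled fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
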