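Package: tavrcea
Title: Decision-Tree Plus Markov Cost-Effectiveness Model of TAVR Versus
    SAVR in Intermediate-Risk Aortic Stenosis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Health-economic evaluation of transcatheter versus surgical
    aortic valve replacement (TAVR vs SAVR) for intermediate-surgical-risk
    aortic-stenosis patients from the Chinese payer perspective. Implements a
    30-day periprocedural decision tree chained to a 59-cycle monthly Markov
    cohort model over five health states, with time-banded transition
    probabilities, 3.7 percent annual cost discounting, a deterministic base
    case, one-way (tornado) sensitivity analysis, probabilistic sensitivity
    analysis with beta-distributed probabilities and gamma-distributed costs,
    cost-effectiveness acceptability curves, device-price scenario analysis,
    and a threshold device-price solver. Parameter sets are declarative
    (JSON/YAML with a flat CSV audit export) and ship with the published
    base-case fixture built in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
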