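Package: ipfcoi
Title: Prevalence-Based Cost-of-Illness Modelling for Idiopathic Pulmonary Fibrosis
Version: 0.1.0
Authors@R: person("Model", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A configurable prevalence-based cost-of-illness pipeline for
    idiopathic pulmonary fibrosis (IPF). Computes annual per-patient costs for
    five components of care (diagnosis, treatment, monitoring, acute
    exacerbations, end-of-life care) separately for each disease course
    (stable, slow, rapid progression), weights end-of-life costs by DEALE
    annual mortality, aggregates course costs by population proportions, and
    runs one-at-a-time (tornado) sensitivity analyses. Includes a synthetic
    multi-round Delphi-panel generator so the whole pipeline can be exercised
    and tested without access to any real expert-panel data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
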