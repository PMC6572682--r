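Package: diabnet
Title: Agent-Based Microsimulation of the Diabetes Epidemic on a Small-World Social Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discrete-time (annual cycle) agent-based model of population
    diabetes dynamics. A synthetic adult population is generated from
    configurable demographic and clinical distributions; lifestyle behaviors
    (smoking, diet, physical activity) spread over a Watts-Strogatz
    small-world social network via a multiplicative social-influence factor
    applied to behavior transition probabilities; health states (body weight,
    hypertension, hypercholesterolemia, glycemic status, nephropathy,
    retinopathy, cardiovascular disease and death) progress through annual
    state-chart transitions. Supports one-shot baseline lifestyle
    interventions at configurable intensity, replicated scenario runs with
    per-year population summaries, intervention comparison and intensity
    sweeps, and cost-savings arithmetic for averted diabetes cases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
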