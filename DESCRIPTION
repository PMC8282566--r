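Package: osteosim
Title: Individual-Level Cost-Effectiveness Microsimulation of Osteoporosis
    Treatment Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A yearly-cycle Markov microsimulation of hip and clinical
    vertebral fractures in older osteoporotic women, built to compare annual
    intravenous zoledronic acid against sequential denosumab followed by oral
    alendronate from a healthcare (and long-term care) payer perspective.
    Models medication persistence and adherence, post-discontinuation offset
    effects, fracture-related excess mortality, costs and utilities; produces
    lifetime discounted costs and QALYs, ICER or dominance classification,
    deterministic one-way sensitivity analyses, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Includes an exact
    expanded-state cohort model used as a verification oracle and a synthetic
    life-table generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
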