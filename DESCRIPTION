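Package: compswitch
Title: Compartmentalization-Induced Bistability in Phosphorylation-Cycle Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how nucleocytoplasmic shuttling turns a monostable
    phosphorylation-dephosphorylation cycle into a bistable switch. Builds the
    compartmentalized mass-action models (the full dimensional system, its
    nondimensional form, and a chain of reductions down to a minimal
    five-variable model), runs the going-up/coming-down stimulus sweep that
    detects hysteresis, samples parameter space by log-uniform Latin hypercube
    sampling, scores hysteresis loops (width, area, branch distances), tests
    per-parameter enrichment (hypergeometric) and influence (Mann-Whitney U),
    and identifies the positive feedback loops required for multistationarity
    through a symbolic Jacobian injectivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
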