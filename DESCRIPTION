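Package: qmlearn
Title: Qualitative Model Learning for Biochemical Pathway Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compose Petri-net models of biochemical pathways from atomic
    binding and unbinding components, simulate them qualitatively over the
    signs quantity space, and learn pathway structure against target
    qualitative states. Provides a component library generator, a
    sign-algebra qualitative engine that enumerates consistent states of a
    model, state-set and structural (arc compression/coverage) scoring, a
    Bayesian score for learning from positive-only qualitative data, a
    (1+1) evolution-strategy top-down composition loop, a simulated-annealing
    bottom-up component explorer with Metropolis acceptance, encoded pathway
    fixtures (enzymatic toy, RKIP-inhibited ERK signalling, methylglyoxal
    detoxification, a synthetic stress-response stand-in), and an integrative
    driver that couples the two search routes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    xml2,
    optparse
Config/testthat/edition: 3
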