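Package: pnpath
Title: Invariant-Based Pathway Analysis of Place/Transition Petri Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Place/Transition Petri-net modelling of signal-transduction
    networks with exact-integer invariant analysis. Computes minimal semi-positive
    place and transition invariants (Farkas elimination), Manatee invariants
    (realizable linear combinations of transition invariants that form complete
    receptor-to-response pathways), outcome classification of pathways, in-silico
    knockout matrices with protein rankings, and UPGMA clustering of knockout
    profiles. Ships a synthetic reconstruction of a TNFR1 signal-transduction
    model (survival / apoptosis / necroptosis switch) plus seeded generators of
    Petri nets with planted invariant structure for testing. Reads and writes
    PNML and a MonaLisa-style SBML dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
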