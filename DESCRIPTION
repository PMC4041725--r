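Package: vhlpn
Title: Qualitative Petri Net Analysis of the VHL Tumor Suppressor Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for qualitative place/transition Petri net modelling of
    signalling and metabolic pathways, built around a hand-encoded core model
    of the von Hippel-Lindau (VHL) tumor suppressor interaction network.
    Provides exact computation of minimal semi-positive T- and P-invariants by
    Farkas elimination, trivial-invariant classification, Tanimoto-coefficient
    clustering of invariant supports, maximal common transition set (MCTS)
    decomposition, structural validity checks (connectedness, homogeneity,
    invariant coverage), seeded token-game simulation, and in-silico knockout
    experiments with qualitative readouts (dead transitions, token
    accumulation and depletion). Readers and writers for PNML, a tabular net
    format, and a read-only Snoopy-style XML dialect are included, together
    with generators of synthetic nets with planted invariants for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
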