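Package: hmmball
Title: Robust Decoding of Labelled Hidden Markov Models via Balls of Labellings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decoding tools for labelled hidden Markov models that target
    approximately correct feature boundaries rather than a single best path.
    Computes the conditional probability of all labellings near a reference
    labelling under the border shift, border shift sum and generalized Hamming
    distances using constrained forward algorithms; finds high-probability
    ball centres by incremental local search with posterior-sampled restarts
    and by an exact dynamic program for regular state-path balls.  Includes
    brute-force enumeration oracles, seeded random-model and membrane-topology
    simulators, topology accuracy measures, readers and writers for a JSON
    model format, FASTA sequences and labelling tables, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    seqinr,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
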