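Package: acdfret
Title: Spectral FRET Analysis for Acridonylalanine-Labeled Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying Forster resonance energy transfer (FRET)
    between intrinsic tryptophan/tyrosine donors and the fluorescent
    noncanonical amino acid acridon-2-ylalanine (Acd) from steady-state
    emission spectra (the Ratio A method), predicting per-construct FRET
    efficiencies from a dimeric structural model via simplified rotamer
    ensembles and donor-acceptor distance distributions, fitting
    time-correlated single photon counting (TCSPC) decays with instrument
    response reconvolution, and normalizing ACMA liposome proton-flux traces.
    Every pipeline stage is paired with a seed-deterministic synthetic-data
    generator carrying its ground truth, so parameter recovery can be tested
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
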