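Package: rnaens
Title: Ensemble Analysis of Hyper-Edited RNA Duplexes from NMR and SAXS Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterise conformational ensembles of double-stranded
    RNA carrying inosine:uridine pairs. Builds parametric A-form duplex
    coordinates with per-residue sugar pucker control, back-calculates NMR
    observables (3J(H1',H2') scalar couplings via the Karplus relation,
    canonical chemical-shift coordinates, NOE effective distances) and SAXS
    observables (Debye profiles, Guinier fits, pair-distance distributions),
    reweights conformer ensembles against experimental averages by the
    maximum-entropy principle, clusters ensembles with quality-threshold
    clustering on torsion/G-vector features, and fits imino-proton
    hydrogen-exchange (CLEANEX-PM) and relaxation decays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
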