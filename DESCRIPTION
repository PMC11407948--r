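Package: quenchbind
Title: Fluorescence-Quenching Binding Analysis and Structural Descriptors for
    Ligand-Serum-Albumin Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for small-molecule binding to serum albumin probed
    by fluorescence titration: inner-filter-effect correction, double-log
    (Hill-type) estimation of the binding constant Ka and site number n,
    quenching and hyperchromicity statistics, synchronous-fluorescence
    quenching ratios, and site-marker competitive displacement. Companion
    structure-side descriptors cover Kabsch superposition RMSD, radius of
    gyration, per-atom RMSF, rotatable-angle statistics, hydrogen-bond
    geometry, binding-energy ledgers and frontier-orbital (HOMO-LUMO) gaps.
    A seeded synthetic-data module generates every input with known ground
    truth so the whole pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
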