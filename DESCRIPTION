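Package: confcount
Title: Conformer Counting Free Energies from Discretized Configurational Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discretizes molecular configurational space into explicit
    torsional-state conformers and tests whether a conformer definition has an
    invariant statistical weight distribution (ISWD), the property that makes
    free energy differences between macrostates computable from conformer
    counts alone. Provides the snapshot-count and conformer-count free energy
    estimators, the pairwise deviation statistics (delta-delta-F and
    delta-delta-S) with cumulative-probability and area-under-curve summaries,
    the conformational-entropy decomposition into a Boltzmann term and a
    Kullback-Leibler deviation, and an exact entropy-enthalpy compensation
    check. Ships exactly solvable Boltzmann systems (double well, independent
    and coupled multi-torsion lattices) so every estimator can be validated
    against brute-force enumeration without any external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
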