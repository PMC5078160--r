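Package: fesbench
Title: Alchemical Free-Energy Estimation, Convergence Diagnostics and
    Binding-Affinity Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis machinery for relative binding-affinity studies of
    congeneric ligand series, built around alchemical free-energy
    perturbation. Computes free-energy differences from per-lambda samples
    with exponential averaging, the Bennett acceptance ratio, thermodynamic
    integration and the multistate Bennett acceptance ratio, with bootstrap
    standard errors; evaluates six phase-space overlap and convergence
    measures per lambda window and proposes lambda refinements; composes
    relative binding free energies over perturbation networks that include
    reference ligands and two-conformer perturbations; assembles composite
    QM/MM binding scores from big-QM, dispersion, basis-set, quasi-RRHO
    thermal, ligand-relaxation and solvation components; and scores
    predictions against experiment (MAD, MADtr, Pearson, Kendall tau-b,
    slope, maximum error) with parametric bootstrap uncertainties and IC50
    conversion. Includes synthetic-data generators with exact ground truth
    (harmonic alchemical states, Crooks-consistent Gaussian work pairs,
    perturbation networks) and packaged HSP90 benchmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
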