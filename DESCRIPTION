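Package: powderdyn
Title: Dynamical Transitions in Simulated Protein Powders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of low-temperature protein dynamics in powder-like
    molecular simulation systems. Computes mass-averaged mean-square
    fluctuations (MSF) from multi-frame trajectories after per-protein rigid
    superposition, estimates block-averaged errors, and detects the two
    dynamical transition temperatures from MSF(T) and enthalpy(T) series by
    segmented linear regression: the low-temperature harmonic slope change
    (T_low) and the protein dynamical transition (T_D), the latter also from
    the heat-capacity jump in enthalpy. Includes residue-level and
    methyl/non-methyl hydrogen decompositions with hydropathy
    classification, a Metropolis water-removal protocol for preparing powders
    at reduced hydration, and a synthetic-data generator that emulates the
    statistical structure of powder trajectories and temperature series for
    testing without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'tables.R'
    'core-model.R'
    'trajectory-io.R'
    'msf-engine.R'
    'transition-detect.R'
    'dehydration.R'
    'powderdyn-package.R'
    'synthetic-data.R'
    'reporting.R'
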