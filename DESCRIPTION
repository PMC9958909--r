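Package: nmrdomain
Title: Domain-Level Protein NMR Analysis: Secondary Shifts, Dynamics,
    Titrations and Size-Exclusion Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the solution-NMR characterization of small protein
    domains. Computes combined Ca/Cb secondary chemical shifts against a
    bundled random-coil reference and calls helix/strand elements by
    consecutive-residue rules; classifies backbone flexibility from
    {1H}15N heteronuclear NOE ratios and delimits rigid cores; tracks
    amide peaks through fast-exchange titrations, computes combined
    1H/15N chemical shift perturbations with mean/2sd significance
    thresholds, and compares binding between ligands and protein
    variants; fits mono-exponential 15N relaxation decays, estimates
    rotational correlation times from R2/R1 and converts them to
    apparent molecular weights; calibrates size-exclusion columns
    (Kav vs log MW) and classifies oligomeric state. A seeded
    synthetic-data module emulates every input (shift tables, hetNOE
    profiles, titration peak trajectories from a single-site binding
    isotherm, relaxation decays from a model-free spectral-density
    oracle, SEC standards) so the whole pipeline is testable without
    spectrometer data. Readers for NMR-STAR v3 chemical-shift loops,
    FASTA, and simple TSV/CSV peak, shift, relaxation and SEC tables
    are included, plus a small command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
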