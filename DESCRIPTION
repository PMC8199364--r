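Package: helixtraj
Title: Trajectory Analysis of Alpha-Helical Bundle Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structural analysis of molecular-dynamics trajectories of
    alpha-helical bundle proteins: Kabsch superposition with RMSD time
    series and relative deviation contrasts between thermal conditions,
    per-residue RMSF, geometric hydrogen-bond detection with
    protein/water class censuses and helical i->i+4 and loop-bridge
    tables, radial distribution functions between hydrophobic C-beta
    atoms, backbone torsion and Ramachandran region analysis, and
    alpha-helix geometry metrics (rise, length, radius, twist,
    end-to-end distance), all summarised by block averaging. Includes a
    synthetic builder that constructs ideal helical hairpin dimers and
    four-helix tetramers from backbone internal coordinates and
    generates noisy trajectories with known ground truth, and a
    config-driven pipeline emitting machine-readable tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
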