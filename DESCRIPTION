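Package: molprep
Title: Small-Molecule Library Preparation for Structure-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Molprep", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts 1D/2D small-molecule representations (SMILES strings or
    flat SDF files) into ensembles of docking-ready 3D models. For every input
    compound the pipeline desalts the record, enumerates ionization states over
    a pH window using a substructure/pKa table, enumerates tautomers with
    rule-based proton shifts and plausibility filters, enumerates unspecified
    tetrahedral stereocenters and cis/trans double bonds, and samples
    alternate non-aromatic ring conformations via distance-geometry embedding,
    force-field optimization, ring-conformation fingerprinting and k-means
    medoid selection. Random sampling plus energy ranking bounds the number of
    variants per compound. Output is SDF (optionally PDB and HTML) with full
    per-model provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
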