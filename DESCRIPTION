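Package: contactlens
Title: Residue-Residue Contact Frequencies for Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes hard-cutoff residue-residue contact frequencies over
    ensembles of molecular dynamics trajectories sharing one topology, keeping
    per-frame track of the atom pairs behind every contact. Provides topology
    fragmentation heuristics that do not rely on the PDB chain field, offline
    transfer of consensus residue nomenclature (GPCRdb, CGN, KLIFS) onto
    arbitrary topologies by pairwise sequence alignment, a flexible residue
    selection grammar, neighborhood / interface / site analyses encapsulated in
    a serializable ContactGroup container, and reporting surfaces: frequency
    tables and spreadsheets, time-traces, distance distributions, contact and
    fragment matrices, flareplot layouts, signed-bfactor PDB heatmaps and
    cross-system comparisons keyed by consensus labels. A synthetic-fixture
    generator plants time-scripted residue-pair distances so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    readxl,
    stats,
    tools,
    utils,
    zip
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
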