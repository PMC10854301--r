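Package: strucdiff
Title: Comparative Solvent-Accessibility and Cavity Analysis of Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two conformations of a multi-chain protein
    complex, such as a GPCR-G protein assembly solved with different G beta
    subunits.  Computes per-atom and per-residue solvent-accessible surface
    area (SASA) by the Shrake-Rupley rolling-probe method, pairs analogous
    residues between structures by sequence alignment, forms per-residue
    SASA ratios with a delta-based exclusion rule and fold-change bins,
    detects enclosed interior cavities and deep pockets on a grid with a
    two-probe (detection/cutoff) definition, and measures inter-subunit
    contacts, hydrogen bonds, C-alpha distances and proline ring pucker
    (endo/exo).  Ships deterministic generators for synthetic test
    structures (ideal helices, helix dimers, sphere cages, open/closed
    complex pairs) so every stage can be validated against analytic and
    brute-force oracles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
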