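Package: spinlabelr
Title: In Silico Spin Labelling and Benchmarking of Nitroxide Label Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the MTSSL (R1) nitroxide spin-label side chain on protein
    structures and benchmarks the two standard in silico labelling paradigms
    against each other and against experimentally observed label conformations.
    Provides a PDB-backed coordinate model with triclinic crystal-cell
    mathematics and P1 packing expansion, an internal-coordinate builder and
    chi1-chi5 measurement for the R1 side chain, accessible-volume sampling and
    rotamer-library placement with Boltzmann clash weighting, ensemble
    comparison metrics (occupancy-weighted spin positions, inter-label distance
    distributions, vector deviations, Shrake-Rupley solvent-accessible surface
    areas, contact listings), a benchmark orchestrator, and a generator of
    synthetic open and tight labelling sites with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
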