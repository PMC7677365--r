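Package: helixcurate
Title: Curation of Helical Cryo-EM Particle Metadata and Atomic-Model
    Comparison Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating per-particle metadata from helical
    cryo-EM refinements of filamentous assemblies such as actin.
    Reads and writes RELION-dialect STAR particle tables, groups
    segments into filaments, detects polarity flips, smooths
    per-particle defocus along each filament with a min/max-trimmed
    local linear regression, estimates per-step helical rise and
    twist from refined Euler angles and origins, rejects outliers
    beyond a standard-deviation multiple, and selects particles
    inside a confidence band. Also provides atomic-model comparison
    metrics (Kabsch superposition, selection RMSD, Shrake-Rupley
    solvent-accessible surface area, buried area, group distances,
    B-factor comparison, van der Waals clash scanning, side-chain
    rotation angles) for PDB and mmCIF models, and a synthetic-data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
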