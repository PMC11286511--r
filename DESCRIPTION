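Package: helifil
Title: Design and Analysis Toolkit for pH-Responsive Helical Protein Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational machinery for de novo pH-responsive
    helical protein filaments: screw-transform algebra for helical symmetry
    (rise/twist decomposition, filament propagation, parameter fitting, ring
    and strand analysis, dock sampling), fragment-based loop closure of
    oligomeric protomers into single chains, protein-protein interface
    metrics (Shrake-Rupley solvent-accessible surface area, shape
    complementarity, buried unsatisfied polar counts, a contact pseudo-energy)
    with a four-criterion design filter pipeline, a cooperative
    protonation-linkage model of pH-triggered disassembly, and an
    event-driven stochastic simulator of fibre depolymerization and
    fragmentation with trace estimators matching single-fibre microscopy
    analyses. Includes deterministic generators for all synthetic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
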