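Package: mocscreen
Title: Automated Screening Workflow for Metal-Organic Cage Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for high-throughput screening of metal-organic cage (MOC)
    subcomponent self-assembly: molecular-formula arithmetic for imine
    condensation products, isotopologue pattern prediction for multiply
    charged ions, speciation assignment from high-resolution mass spectrometry
    peak lists with charge-state verification, 1H NMR conversion triage and
    tetrahedron:helicate speciation ratios, a plate-based single-point NMR
    host-guest association-constant assay, screen outcome reporting, and
    seeded synthetic-data generators so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    withr
Config/testthat/edition: 3
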