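Package: chemcheck
Title: Validation and Standardization of Chemical Structure Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Batch validation of chemical structure records in MDL molfile,
    SDF and SMILES form. Parses V2000 connection tables without normalizing
    away defects, evaluates dictionary rules written as SMARTS patterns at
    three severities (Information, Warning, Error), runs a wedge/hash
    stereochemistry battery, detects ambiguous dearomatization, checks
    competitive ionization against a ranked acid/base table and reprotonates
    to the canonical protonation state, classifies six-membered-ring
    depictions by ring-walking turn signatures (chair, boat, Haworth,
    mirrored L-pyranose), cross-validates depositor SMILES and InChI fields
    against the connection table, and aggregates a filterable JSON report.
    Substructure matching, SMILES parsing and standard InChI generation are
    delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package importable from
    the 'python' (or 'python3') executable on the PATH.
Config/testthat/edition: 3
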