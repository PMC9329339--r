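Package: mms3d
Title: Executable Registry, Validator and Crosswalks for the 3D Microscopy
    Metadata Standards
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An executable encoding of the 3D Microscopy Metadata Standards
    (3D-MMS), the 91-field, seven-category metadata standard for
    three-dimensional light-microscopy datasets used by the Brain Image
    Library. Provides the versioned field registry as queryable data,
    JSON-Schema emission (one schema per category plus a combined record
    schema), a rule-based record validator with a fixed issue catalog and
    machine-readable reports, identifier checksum verification (ORCID and
    ISNI ISO 7064 mod 11-2 check digits, ROR, RRID and GRID syntax),
    conversion between the tabular submission layout and the JSON record
    form, a DataCite metadata-kernel export for DOI minting, an OME Data
    Model correspondence report, a seed-reproducible synthetic record
    generator with labeled fault injection, and a command-line interface
    with stable exit codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    tibble,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
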