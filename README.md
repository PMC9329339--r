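# mms3d — executable registry and toolchain for the 3D Microscopy Metadata Standards

Three-dimensional light-microscopy datasets (light sheet, confocal,
multiphoton, serial two-photon tomography, …) are only reusable when the
metadata around them — who made them, under what funding, on which
instrument, at what voxel size, from which organism — is recorded
consistently. The 3D Microscopy Metadata Standards (3D-MMS) define that
record: **91 metadata fields in seven categories** (Contributors,
Funders, Dataset, Image, Instrument, Publication, Specimen), with a
required submission core, controlled vocabularies, conditional
requirements, and a subset of 19 required fields whose DataCite
equivalents allow a DOI to be minted for the dataset.

`mms3d` is for data curators, repository engineers and imaging labs who
need to *enforce* that standard rather than read about it. The package
encodes the full standard as data and makes every part of it
executable:

* **Registry** — `build_default_registry()` returns the versioned
  (1.0.0, semantic versioning) field registry; `count_fields()`,
  `get_field()` and `export_registry_json()` query and dump it.
* **Validation** — `validate_record()` applies the full rule catalog
  (presence, conditional requirements, vocabularies, RGB color
  triplets, positive step sizes, NCBI taxonomy syntax, ORCID/ISNI
  ISO 7064 mod 11-2 check digits, SPDX hints, cardinality) and returns
  an ordered machine-readable report with `error` / `warning` /
  `advice` severities and three profiles (`bil`, `doi_only`,
  `lenient`).
* **JSON Schema** — `emit_json_schema()` derives one draft 2020-12
  schema per category plus a combined `record_schema.json`;
  `validate_against_schema()` is a self-contained evaluator for that
  dialect subset, usable as a second engine against the rule validator.
* **Interchange** — `parse_record()` / `serialize_record()` for the
  JSON record form; `read_tabular()` / `write_tabular()` (+`_csv`) for
  the per-category tabular submission layout;
  `attach_common_metadata()` to stamp shared Contributors/Funders onto
  a series of records.
* **Crosswalks** — `export_datacite()` maps a record onto the DataCite
  metadata kernel (JSON canonical, XML via `datacite_xml()`);
  `mapping_counts()` and `ome_report()` cover the OME Data Model
  correspondence.
* **Synthesis** — `generate_valid_record()`, `inject_errors()` and
  `generate_corpus()` produce seed-reproducible valid records and
  ground-truth-labeled corrupted records, so pipelines can be tested
  with no external data.
* **CLI** — `exec/mms3d` exposes `validate`, `convert`, `schema`,
  `export-datacite`, `stats` and `generate` with stable exit codes
  (0 valid, 1 validation errors, 2 usage/IO).

## The standard in numbers

The registry self-checks these invariants at build time: 91 fields;
per-category totals 9/5/15/33/12/5/12; required submission sets per the
standard's required-field table (Contributors 9, Dataset 5, Funders 5,
Instrument 2, Image 8, Specimen 5); 19 DOI-supporting required fields;
all Publication fields optional; 25 pinned DataCite mappings
(Contributors 9 + Funders 5 + Dataset 8 + Publication 3) and 27 pinned
OME mappings (Instrument 12 + Image 15). Conditional requirements are
explicit: Funders fields are required only when government funding is
declared (`fundingDeclared`); `nameIdentifier`/`nameIdentifierScheme`
are required for Personal names; `rightsURI`/`rightsIdentifier` apply
when a common license is used.

## Worked example

```r
library(mms3d)
reg <- build_default_registry()
reg
#> <mms_registry> 3D-MMS v1.0.0: 91 fields in 7 categories
#>   Contributors  9 fields (9 required for submission, 9 DOI)
#>   Funders       5 fields (5 required for submission, 5 DOI)
#>   Dataset      15 fields (5 required for submission, 5 DOI)
#>   Image        33 fields (8 required for submission, 0 DOI)
#>   Instrument   12 fields (2 required for submission, 0 DOI)
#>   Publication   5 fields (0 required for submission, 0 DOI)
#>   Specimen     12 fields (5 required for submission, 0 DOI)

rec <- generate_valid_record(generator_config(seed = 7))
rec
#> <mms_record> 2 contributor(s), 2 funder(s), 1 publication(s); 3 channel(s); funding declared: yes
#>   Title: A bilateral 3D image volume of the thalamus
#>   populated: Dataset 9, Image 8(+3 ch), Instrument 9, Specimen 10 fields

bad <- inject_errors(rec, c("NO_CREATOR", "AGE_NEGATIVE"), seed = 1)
validate_record(bad$record, reg, profile = "bil")
#> <mms_report> profile=bil verdict=INVALID (2 errors, 0 warnings, 0 advice)
#>   [error] NO_CREATOR Contributors: no contributor is flagged as a creator; at least one is required
#>   [error] AGE_NEGATIVE Specimen.Age: Age must be non-negative (or "unknown"), got -4
```

The report says the corrupted record can no longer be submitted: the
standard requires at least one contributor flagged as a creator (that
entry also becomes the DataCite `creators` element when a DOI is
minted), and the donor age must be a non-negative number or the literal
`"unknown"`. Repairing both fields makes the record validate clean
again, after which `export_datacite(rec)` emits the DOI metadata
kernel.

From a shell:

```sh
mms3d stats --category Image          # 33
mms3d schema --out schemas/           # writes the 7+1 JSON-Schema files
mms3d validate --input record.json --profile bil --format json
```

## Scope notes

The package implements the standard itself: it does not talk to any
submission portal, mint DOIs, query NCBI taxonomy, or emit OME-XML
instance documents (record-level metadata lacks the pixel-data context
OME-XML requires; the OME direction is a term mapping and per-record
report). See `vignettes/mms3d-methods.Rmd` for design decisions and
limitations.
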