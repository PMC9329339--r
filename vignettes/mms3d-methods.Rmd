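---
title: "mms3d: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mms3d: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mms3d)
```

This vignette explains how the package models the 3D Microscopy
Metadata Standards (3D-MMS), which design decisions were genuinely open
and how they were settled, what the synthetic-data generator does and
does not emulate, and the package's known limitations.

## The standard as data

The unit of the model is a *field specification*: name, category,
definition, value kind (free text, closed vocabulary, or number),
vocabulary, advisory "suggested values", requirement level,
condition, scope, repeatability, DOI-support flag, DataCite property,
OME term, and units. `build_default_registry()` assembles 91 such
specifications into the seven categories of the standard, in its
printed order, and refuses to return anything if a structural
invariant fails — a registry that cannot reproduce the standard's
counts is a bug, not a warning.

```{r}
reg <- build_default_registry()
count_fields(reg)
count_fields(reg, requirement = "bil_required", doi_support = TRUE)
```

### Requirement semantics

Three levels are modeled. `required` fields must always be present for
submission. `conditional` fields are required only under a stated
condition, of which the standard has three kinds: the five Funders
fields apply when the project is government-funded;
`nameIdentifier`/`nameIdentifierScheme` apply to Personal names; and
`rightsURI`/`rightsIdentifier` apply when a common license is used.
Everything else is `optional`. The filter `bil_required` (= not
optional) reproduces the standard's required-field table: 9 + 5 + 5 +
2 + 8 + 5 = 34 fields. The standard's own prose also cites a headline
count of 31 required fields, which no partition of the conditional
fields reconciles with the table; this package follows the table — the
only internally consistent enumeration — and records the headline
number as a known inconsistency that is asserted nowhere.

### The synthesized optional roster

The standard prints exact names only for the 34 required-table fields;
the optional fields are described in prose (modality and technique,
methods fields, pixel counts, file/timepoint/channel/slice counts,
oblique qualifiers, landmarks, objective/detector/illumination
details, genotype/organ/location/atlas, publication identifiers). The
registry synthesizes camelCase names consistent with that prose
(`generalModality`, `sizeX`, `numberOfChannels`, `objectiveNA`,
`landmarkX`, `relatedIdentifierType`, …), chosen once so that the
per-category totals (15/33/12/5/12) and the pinned crosswalk counts
(8 Dataset DataCite fields; 15 Image and 12 Instrument OME fields) are
satisfied exactly. Every synthesized field carries provenance
`"synthesized-from-prose"` in the registry dump, so the roster is
auditable and individually replaceable without touching any code.

### Scopes and repeatability

The standard states that fields repeat but prints no per-field counts,
so repeatability follows entity semantics: contributors, funders,
publications, channels and landmarks are unbounded repeatable groups
(scopes `entry`, `channel`, `landmark`); dataset-level scalars (title,
abstract, axes, step sizes) occur once (`record` scope, maximum one
occurrence). A contributor with several roles is represented as
several entries, matching the standard's flat one-line-per-role
layout. `Creator` is modeled as a per-contributor flag serialized as
`"Yes"`/`"No"`.

## Validation

`validate_record()` applies a fixed catalog of fourteen rules
(`fault_codes()`); every problem is reported, nothing raises, and
multiple issues on one field are all kept. Report ordering is
deterministic — category order, then field order, then catalog order —
so identical records yield byte-identical reports.

Decisions worth calling out:

* **Funders conditionality.** The standard has no machine-readable
  trigger for "the project is government funded", so the record
  carries an explicit `funding_declared` flag (serialized as top-level
  `fundingDeclared`, default `TRUE`, since the repository profile
  targets government-funded submissions). `COND_FUNDERS` fires only
  when the flag is set.
* **Common-license conditionality.** "If using a common license" is
  likewise undetectable from the record itself, so
  `rightsURI`/`rightsIdentifier` are never reported missing; instead a
  *present* `rightsIdentifier` that does not look like an SPDX token
  draws a `SPDX_HINT` warning.
* **Vocabulary casing.** Spreadsheet-sourced data drifts in case, so
  vocabulary matching is case-insensitive: a case-only mismatch is
  advice (the record stays valid), a genuinely foreign value is an
  error.
* **Suggested values.** The modality/technique/instrument-detail
  lists are advisory by construction (the standard types these fields
  as free text), so `SUGGESTED_VALUE_MISS` is advice-level and can
  never invalidate a record.
* **Profiles.** `doi_only` restricts checking to the DOI-supporting
  fields plus the creator and identifier rules — exactly what
  `export_datacite()` needs; `lenient` downgrades the two
  conditional-requirement rules to warnings. Error keys under
  `lenient` are a subset of those under `bil` by construction, and the
  test suite asserts it.

### Identifier checksums

ORCID and ISNI carry an ISO 7064 mod 11-2 check character; the package
computes it with the Horner-style running remainder and validates the
final character, tolerating leading resolver URLs. ROR (`0` + 8
alphanumerics), RRID (`RRID:` prefix) and GRID (`grid.` prefix) are
syntactic checks only. The test suite cross-checks the checksum
against a closed-form power-sum oracle (an algorithmically different
evaluation of the same standard) on hundreds of generated identifiers
per run; species-to-taxonomy semantic agreement is deliberately out of
scope (the taxonomy rule is digits-only syntax).

## JSON Schema emission and the second engine

Schemas are emitted in the draft 2020-12 dialect: enumerations for
vocabulary fields, `required` lists for unconditional fields, arrays
for repeatable groups, `exclusiveMinimum` for step sizes, and the
conditional requirements as `if`/`then` constructs (`Personal` →
identifier fields; `fundingDeclared` → non-empty, complete Funders).
The at-least-one-creator rule is expressed with `contains`. The
combined `record_schema.json` composes the seven category schemas by
`$ref` into `$defs`; the standalone Funders schema requires all five
fields (it describes the government-funded case), while the combined
schema gates that requirement on the flag.

`validate_against_schema()` is a generic evaluator for exactly this
dialect subset. It interprets the schema document and shares no code
with either the emitter or the rule validator, which is what makes the
agreement tests meaningful: clean generated records must pass the
emitted combined schema, and records with an unconditionally required
field deleted must fail it. The schema is intentionally *weaker* than
the rule validator where schema expression would be awkward (e.g. RGB
range 0–255, checksum digits), so schema-pass does not imply
rule-valid — the implication tested is rule-valid ⇒ schema-pass, and
required-field faults ⇒ schema-fail.

## Tabular carrier

The physical carrier is a directory of per-category CSV files (UTF-8,
comma, quoted as needed): testable to byte-exactness without any
binary-format coupling. The layout is declared normative for this
package: one header row of registry field names per category; one row
per entry for Contributors/Funders/Publication; one row for
Dataset/Instrument/Specimen; and an interleaved Image table where
record-scoped values sit on row 1 and channel/landmark columns fill as
many rows as there are channels/landmarks. An eighth small
`Submission` table carries the `fundingDeclared` flag so that
tabular ↔ record round trips preserve it while the seven category
tables keep exactly the registry headers. Multi-sheet workbooks are
not read or written; converting a workbook to per-sheet CSV is a
one-liner in any spreadsheet tool and keeps this package's carrier
fully text-based.

## Crosswalk scoping

The crosswalk contains only the mappings the standard pins per
category: 25 DataCite rows (Contributors 9, Funders 5, Dataset 8,
Publication 3) and 27 OME rows (Instrument 12, Image 15). The
standard's prose also cites totals of 27 DataCite-equivalent and 41
OME-mappable fields without identifying the remaining fields per
category; those unpinned mappings are *not* invented here, and
`mapping_counts()` therefore reports 25 and 27. `export_datacite()`
is lossless over DOI-supporting fields (the tests sweep every
populated value into the output document) and refuses records that
fail the `doi_only` profile, attaching the report to the error
condition. The OME direction is a registry-level term mapping plus a
per-record report (`ome_report()`); no OME-XML instance document is
produced because record-level metadata lacks the pixel-data context
OME-XML requires.

## The synthetic-data generator

`generate_valid_record()` emulates a plausible repository submission:
a small author list with ORCID-identified Personal and ROR-identified
Organizational contributors (at least one creator), government funding
declared with complete funder entries, a licensed dataset with an
abstract of ≥ 100 words (the standard's recommendation; the default
`abstract_words = 105`), one to four channels with RGB display colors,
log-uniform step sizes in 0.1–10 µm laterally and 0.2–50 µm axially,
and a specimen drawn from a small table of common model organisms with
syntactically consistent taxonomy codes. Optional fields fill
independently with probability 0.5. Each record's stream derives from
(master seed, record index), so corpora are byte-reproducible and
order-insensitive.

`inject_errors()` gives every validator rule a corruption recipe with
a ground-truth label (path + code). Recipes deliberately target
disjoint fields so that stacked faults remain independently
detectable; the corpus-level test asserts detection recall 1 over all
labels, and the monotonicity property (an extra fault never decreases
the issue count) follows from the disjointness.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: free-text noise (typos, encoding damage,
HTML fragments pasted from lab wikis), semantically wrong but
syntactically fine values (a mouse dataset with a human taxonomy
code), partially filled spreadsheet rows with shifted columns, and the
long-tail heterogeneity of real instrument descriptions. The validator
is exercised against the fault classes in its catalog, not against
adversarial input.

## Numerical and procedural choices

* No floating-point tolerances are needed anywhere: equality checks
  are on serialized bytes, and the serializer prints numbers at full
  round-trip precision (CSV cells fall back to `%.17g` only when the
  default decimal text would not round-trip).
* Corpus sizes in the shipped tests: 200 records for round-trip and
  detection-recall checks, 100 for schema agreement, 1,000 identifiers
  for checksum agreement — sizes at which every property is exercised
  across all recipes and branch combinations while the whole suite
  runs in about a minute.
* Degenerate inputs: parsing is total (never raises on content), an
  empty record is serializable and produces the header-only tabular
  template, an empty report summarizes to an empty mapping, and
  `attach_common_metadata()` on an empty record list returns an empty
  list.
* Ties/ordering: report ordering is fixed (category, field, catalog);
  JSON key order is registry order; these choices make all outputs
  byte-deterministic, which the tests assert.

## Known limitations

* The optional-field roster is synthesized from prose; if the
  standard's official field list is consulted later, names can be
  swapped in the registry data without code changes, but persisted
  records written with the synthesized names would need a rename pass.
* The two unpinned DataCite and fourteen unpinned OME mappings are
  absent by design (see crosswalk scoping above).
* Vocabulary enumerations in the emitted schemas are case-sensitive,
  while the rule validator canonicalizes case with an advice note; a
  case-drifted record is therefore rule-valid but schema-invalid.
  Canonicalize (parse + serialize) before schema-validating
  spreadsheet-sourced data.
* The CLI covers single records; batch validation is a shell loop over
  `mms3d validate`, by design (stable exit codes are the contract).
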