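---
title: "Structured clinical sequencing reports and their FHIR mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured clinical sequencing reports and their FHIR mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqreport)
```

## The problem and the model

A clinical genomic sequencing report communicates a patient's NGS findings —
which somatic variants were seen, how they are classified, and what therapy
they suggest — from a sequencing facility into an electronic health record.
`seqreport` models that report as a registry of *data elements* split into
two field classes: **required** elements that clinical use depends on
(subject identification, the order and its authorization, the performing
laboratory, the biomaterial, the variant block, recommended treatments) and
**optional** elements aimed at research use (run-level sequencing detail,
platform descriptors, quality-control metrics, genomic biomarkers). Each
element carries a metadata binding naming the terminology or format that
governs its values: ISO/TS 22220-style subject identification, ISO 8601
dates, HL7 v3 race codes, HGNC gene identifiers, HGVS variant nomenclature,
or external database ids. The shipped registry holds 32 required and 29
optional elements.

The exchange format is HL7 FHIR in its STU3 dialect. Every element maps to a
slot on one of eight resource types; where a core FHIR element fits, the
mapping *reuses* it, and where none exists, the mapping defines a named,
URL-identified *extension* (the FHIR Genomics idiom: for instance the
variant name has no core home on Observation and lives in
`Observation.extension(observation-geneticsDNASequenceVariantName)`).

### Elements versus slots

The registry has 61 elements, but the mapping table has 90 rows, because the
table's unit is the mapped FHIR *slot* and one element can occupy several:

* subject demographics are reachable through the printed dereference path
  `DiagnosticReport.subject(patient)` *and* directly on the Patient resource
  (identifier and birth date as core elements; sex and ethnicity as Patient
  extensions, since an ISO/TS 22220 sex code such as `"1"` has no core STU3
  field);
* the variant classification, printed as `"Tier 1 (Pathogenic,
  Identified)"`, expands into the three sub-extensions
  `Tier`, `Pathogeny` and `ClinicalRelavance` (the last spelled as in the
  source profile set) of one complex extension;
* quality-control metrics expand into seven named sub-extensions
  (mean depth, target coverage, uniformity, Q30 fraction, total reads,
  mapped fraction, duplication rate);
* platform descriptors surface both as MolecularSequence extensions and on a
  Device resource; each recommended treatment is a free-standing Medication
  entry referenced from a DiagnosticReport extension.

This accounting yields exactly the per-resource counts the package treats as
its design contract — 26 reused + 15 extended slots for the required fields
and 28 + 21 for the optional fields, 90 in all — which the test suite and
the acceptance script verify by independently recounting the exported table.
`map_element()` returns an element's *primary* slot (its canonical storage
location); `element_slots()` returns all of them. Which concrete elements
fill the non-worked-example slots is not publicly enumerable, so those
entries are synthesized with field-plausible names and flagged
`provenance = "reconstructed"` in the registry, while every element whose
name and binding are printed in the published mapping example is flagged
`provenance = "paper"`.

## Path dialect and the walker

Each mapping row carries two path strings. `fhir_path` is the display
dialect exactly as mapping tables in this space print it, with
`extension(name)` segments and the `subject(patient)` dereference. A parsed
`structural_path` backs it, evaluated by `walk_bundle_path()` over the
generic resource model: plain segments index body fields, `field(type)`
follows an internal reference, `extension(name)` matches the URL basename,
a segment after an extension names a sub-extension, and `component(code)`
selects an Observation component. Because the walker knows nothing about the
builder, it doubles as an independent field-placement oracle in the tests:
for every populated element, walking each of its slots must recover the
corresponding (component of the) report value.

## Validation semantics

`validate_report()` returns findings, never throws. One `missing-required`
issue is emitted per absent required element; populated fields are checked
against their bindings (`bad-format` for dates, HGNC ids, race-code shape
and unparseable HGVS; `bad-code` for out-of-set coded values). Three
choices deserve a note:

* **Zero variants versus no variant section.** An explicitly empty variant
  list is a legitimate clinical statement ("no reportable variants") and
  validates cleanly; an absent variant section is non-conformant and yields
  one issue per variant-block element. This is why an entirely empty report
  yields exactly 32 issues.
* **Variant effect is free text.** Its binding is "Text", so unrecognized
  effects produce only a warning-level suggestion against a small advisory
  vocabulary, never an error.
* **Race codes are checked lexically** (`<digits>-<digit>`), with a bundled
  micro-valueset for display only; no terminology server is consulted.

`build_bundle()` refuses any report with error-severity issues, making
validation exactly the builder's gate. `coverage_summary()` audits a bundle
slot by slot in the same shape as `mapping_statistics()`, so a fully
populated bundle reproduces the mapping counts exactly and an empty bundle
is all zeros.

## The synthetic generator

`generate_reports()` stands in for a sequencing facility's feed. Its
defaults describe a small tumor-panel service: 1–3 variants per report drawn
from a bundled 20-gene HGNC micro-list, cDNA changes from a compact
substitution grammar with an 80% chance of an accompanying protein change,
a 50% chance that the facility pads the substitution sign with spaces (the
raw dialect the worked example uses), classifications drawn uniformly from
the tier/pathogeny/relevance value sets, a 50% chance of a research block,
and `missingness` applied to optional fields only. Those defaults were
chosen once as a realistic desk-scale service profile; the test suite runs
corpora of 30–200 reports, sizes picked so the full suite stays
interactive-fast.

The generator emulates structure, not biology: gene/variant pairs are not
constrained to real hotspots, classifications are independent of the
variant, and coordinates in the research block are arbitrary. Passing
round-trip and placement properties on this corpus therefore demonstrates
that the mapping machinery is lossless and total over the registry — it
says nothing about the clinical plausibility of real report content.

The worked-example fixture reproduces the published specification example
(subject 12345678 / Gildong Hong / 1947-04-29 / sex "1" / ethnicity
"2040-4"; BRAF HGNC:1097, `c.1799T > A_p.V600E`, COSM476). The example
prints no classification, order, specimen or treatment values, so the
fixture completes them — the classification with the companion example
"Tier 1 (Pathogenic, Identified)", the treatment with vemurafenib — to
obtain one fully conformant anchored fixture.

## Numerical and design choices

* **JSON canonicalization.** Keys are emitted in fixed schema order;
  integers are widened to doubles and length->1 atomic vectors become JSON
  arrays at construction time, so `from_json(to_json(x))` is `identical()`
  on all resources, not merely equivalent.
* **Raw versus normalized notation.** The raw dialect string
  (`c.1799T > A_p.V600E`) is stored and displayed verbatim; normalized HGVS
  (`c.1799T>A`, `p.V600E`) is derived at construction. No reference-sequence
  validation, left-shifting or transcript resolution is attempted.
* **Bundle type.** Both collection and transaction bundles are supported;
  collection is the default since nothing in the exchanged content requires
  transactional semantics.
* **Repository.** Storage is in-memory (with an optional JSON-lines
  snapshot); update increments the version by exactly one and history is
  append-only. Delete exists only as a soft-delete behind
  `allow_delete = TRUE`, reconciling a server surface that lists
  create/history/read/search/update with a build environment that also
  exercised delete. `authorize()` is a deterministic token-table stub in
  place of OAuth 2.0; TLS is out of scope.
* **Search** supports subject, code, gene-extension value and an
  effective-date range with AND semantics — a deliberately small set, since
  the originally supported server parameters are unstated; results are
  defined (and tested) as equal to a brute-force linear scan.
* **ProcedureRequest naming.** The STU3 name ProcedureRequest is canonical
  throughout (matching the mapping counts); later releases rename it
  ServiceRequest.
* **CLI.** The command-line layer is a thin Rscript over exported functions.
  An HTTP facade is intentionally absent: the library API is the contract,
  and the repository module covers the server operation set in-process.

## Limitations

* The reconstructed element names (everything outside the published mapping
  example) are plausible, not authoritative; consumers should treat
  `provenance = "reconstructed"` entries as placeholders with correct
  cardinalities and bindings rather than as standard text.
* No FHIR StructureDefinition conformance resources are generated; extension
  definitions are exposed as a data frame, not profile files.
* HGVS handling is syntactic only; terminology checks are lexical or
  value-set based, with no external terminology services.
* The FHIR dialect is a pragmatic STU3 subset (eight resource types plus
  Bundle, JSON only, no XML/RDF, no FHIRPath engine).
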