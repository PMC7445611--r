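# seqreport

Clinical next-generation-sequencing (NGS) results are still widely delivered
as PDFs or free text, which makes them invisible to the electronic health
record. `seqreport` implements the ISO/TS 20428 structured clinical genomic
sequencing report as a machine-processable data model, together with a
bidirectional mapping to HL7 FHIR (STU3-dialect) Genomics resources, so that
report content can be produced, exchanged, validated, and rendered without
ever passing through an unstructured document.

It is aimed at clinical-genomics informaticians and EHR integrators who need
to move tiered somatic variant reports (gene, HGVS notation, variant database
id, pathogenicity/tier/clinical-relevance classification, recommended
treatments) between a sequencing facility and a clinician-facing system.

## What is in the box

- **Element registry** — 32 required (clinical) and 29 optional (research)
  data elements, each with a section label and a terminology binding
  (ISO/TS 22220 identification, ISO 8601 dates, HL7 v3 race codes, HGNC,
  HGVS, database ids), plus controlled value sets: 5 pathogenicity codes
  (*Pathogenic … Benign*), 4 clinical-relevance codes (*Identified … Not
  identified*), the ISO/TS 22220 sex code table, and a 4-level tier set.
- **Mapping table** — one row per mapped FHIR slot: the target resource, the
  path expression (in the `extension(name)` / `subject(patient)` dereference
  dialect), and whether the slot reuses a core FHIR element or defines an
  extension. The per-resource counts are: required fields —
  ProcedureRequest (3, 0), DiagnosticReport (12, 5), Observation (8, 8),
  Medication (1, 0), Patient (2, 2), totals 26 reused + 15 extended;
  optional fields — Condition (1, 0), DiagnosticReport (2, 2),
  MolecularSequence (16, 10), Observation (6, 6), Device (3, 3), totals
  28 reused + 21 extended; 90 slots in all.
- **FHIR model** — a minimal generic STU3-dialect resource/bundle container
  with URL-identified extensions, canonical JSON serialization and internal
  reference validation.
- **Builder / extractor** — `build_bundle()` places every populated report
  element at its mapped slot (one Observation-genetics per variant, subject
  demographics on a Patient dereferenced from `DiagnosticReport.subject`,
  the classification triple as sub-extensions `Tier`/`Pathogeny`/
  `ClinicalRelavance`); `extract_report()` inverts it.
- **Validation** — per-element conformance issues (missing required fields,
  value-set and format violations) and a slot-coverage audit of any
  bundle.
- **Repository** — an in-memory FHIR-style store with create, read, update,
  history and search (plus a deterministic token stub in place of OAuth 2.0).
- **Fixtures** — the fixed worked example (BRAF c.1799T>A / p.V600E,
  COSM476, "Tier 1 (Pathogenic, Identified)"), a seeded synthetic report
  generator, a VCF + annotation-sidecar ingestion shim, and a plain-text /
  HTML clinician summary renderer.

## Worked example

```r
library(seqreport)

we <- worked_example()
nrow(validate_report(we))        # 0 — the fixture is fully conformant
bundle <- build_bundle(we)
bundle
#> <FHIR Bundle: collection> 5 entries: Patient, ProcedureRequest,
#>   DiagnosticReport, Observation, Medication

mapping_statistics()$required
#>     resource_type elements extensions
#>  ProcedureRequest        3          0
#>  DiagnosticReport       12          5
#>       Observation        8          8
#>        Medication        1          0
#>           Patient        2          2
#>             Total       26         15

cat(render_summary(bundle)$text)
#> == VARIANT RESULTS ==
#> BRAF (HGNC:1097)  c.1799T > A_p.V600E  [Substitution (missense)]  Tier 1 (Pathogenic, Identified)  COSM476
#>
#> == INTERPRETATION SUMMARY ==
#> BRAF p.V600E activating mutation detected; BRAF-targeted therapy is indicated.
#>
#> == TEST INFORMATION ==
#> Subject: Gildong Hong (12345678), born 1947-04-29
#> Test: solid-tumor-ngs-panel  Report: RPT-2026-0001  Status: final  Issued: 2026-03-20
#> Specimen: Tumor tissue (FFPE) (SPC-88421), collected 2026-02-27
#> Performing laboratory: University Hospital Molecular Pathology Laboratory
#> Recommended treatment(s): Vemurafenib
```

The variant section reproduces the report's raw notation dialect
(`c.1799T > A_p.V600E`) verbatim, while the stored record carries the
normalized HGVS strings (`c.1799T>A`, `p.V600E`). Extraction inverts the
build exactly:

```r
identical_report <- extract_report(bundle)   # equals worked_example()
```

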