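Package: seqreport
Title: Structured Clinical Genomic Sequencing Reports with FHIR Genomics Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the ISO/TS 20428 structured clinical genomic sequencing
    report as a validated, machine-processable data model, together with a
    bidirectional mapping to HL7 FHIR (STU3-dialect) Genomics resources and
    extensions. Provides the data-element registry with terminology bindings and
    controlled value sets, the element-to-FHIR mapping table with per-resource
    statistics, a minimal generic FHIR resource and bundle model with JSON
    serialization, a report-to-bundle builder with round-trip extraction,
    conformance validation, an in-memory FHIR-style repository (create, read,
    update, history, search), a seeded synthetic report generator, a VCF
    ingestion shim, and a clinician summary renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
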