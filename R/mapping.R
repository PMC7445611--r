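# Element -> FHIR (STU3-dialect) mapping table.
#
# The table stores one row per mapped FHIR *slot*. A registry element may occupy
# more than one slot: subject demographics are reachable both through
# DiagnosticReport.subject(patient) (the dereference path the standard's mapping
# example prints) and directly on the Patient resource; the variant
# classification expands into three sub-extensions (Tier, Pathogeny,
# ClinicalRelavance); quality-control metrics expand into seven sub-extensions;
# platform descriptors surface both as MolecularSequence extensions and on a
# Device resource. element_id is therefore non-unique across rows. The
# per-resource (reused, extended) slot counts are the checkable surface:
# required 26+15=41, optional 28+21=49, 90 slots in total.
#
# Each row carries two path expressions: `fhir_path`, the display dialect with
# `extension(name)` and `subject(patient)` dereference notation, and
# `structural_path`, the parsed form the bundle walker evaluates (extension
# segments name the full URL basename; a segment after an extension segment is a
# sub-extension; `component(code)` selects an Observation component).

#' Base URL under which the package's extension definitions live
#' @export
SEQREPORT_EXTENSION_BASE <- "https://seqreport.example.org/fhir/StructureDefinition/"

.ext_url <- function(name) paste0(SEQREPORT_EXTENSION_BASE, name)

.mapping_rows <- function() {
  m <- function(element_id, field_class, resource_type, fhir_path,
                structural_path = fhir_path, mapping_kind = "reuse",
                extension_url = "", component = NA_character_,
                primary = FALSE) {
    list(element_id = element_id, field_class = field_class,
         resource_type = resource_type, fhir_path = fhir_path,
         structural_path = structural_path, mapping_kind = mapping_kind,
         extension_url = extension_url, component = component,
         primary = primary)
  }
  ext <- function(...) m(..., mapping_kind = "extension")
  rows <- list(
    ## ---- required field slots (41) ----
    m("order.order_id", "required", "ProcedureRequest", "ProcedureRequest.identifier", primary = TRUE),
    m("order.order_date", "required", "ProcedureRequest", "ProcedureRequest.authoredOn", primary = TRUE),
    m("order.ordering_clinician", "required", "ProcedureRequest", "ProcedureRequest.requester", primary = TRUE),

    m("subject.identifier", "required", "DiagnosticReport",
      "DiagnosticReport.subject(patient)",
      "DiagnosticReport.subject(patient).identifier", primary = TRUE),
    m("subject.identifier", "required", "Patient", "Patient.identifier"),
    m("subject.identifier", "required", "Observation",
      "Observation.subject(patient)", "Observation.subject(patient).identifier"),
    m("subject.name", "required", "DiagnosticReport",
      "DiagnosticReport.subject(patient)",
      "DiagnosticReport.subject(patient).name", primary = TRUE),
    m("subject.birth_date", "required", "DiagnosticReport",
      "DiagnosticReport.subject(patient)",
      "DiagnosticReport.subject(patient).birthDate", primary = TRUE),
    m("subject.birth_date", "required", "Patient", "Patient.birthDate"),
    m("subject.sex", "required", "DiagnosticReport",
      "DiagnosticReport.subject(patient)",
      "DiagnosticReport.subject(patient).extension(patient-sexIso22220)",
      primary = TRUE),
    ext("subject.sex", "required", "Patient",
        "Patient.extension(patient-sexIso22220)",
        extension_url = .ext_url("patient-sexIso22220")),
    ext("subject.ethnicity", "required", "DiagnosticReport",
        "DiagnosticReport.subject(patient).extension(ethnicity)",
        "DiagnosticReport.subject(patient).extension(patient-ethnicity)",
        extension_url = .ext_url("patient-ethnicity"), primary = TRUE),
    ext("subject.ethnicity", "required", "Patient",
        "Patient.extension(patient-ethnicity)",
        extension_url = .ext_url("patient-ethnicity")),

    ext("order.legally_authorized_person", "required", "DiagnosticReport",
        "DiagnosticReport.extension(diagnosticreport-legallyAuthorizedRepresentative)",
        extension_url = .ext_url("diagnosticreport-legallyAuthorizedRepresentative"),
        primary = TRUE),
    m("order.performing_laboratory", "required", "DiagnosticReport",
      "DiagnosticReport.performer", primary = TRUE),

    m("report.report_id", "required", "DiagnosticReport", "DiagnosticReport.identifier", primary = TRUE),
    m("report.status", "required", "DiagnosticReport", "DiagnosticReport.status", primary = TRUE),
    m("report.test_code", "required", "DiagnosticReport", "DiagnosticReport.code", primary = TRUE),
    m("report.issued_date", "required", "DiagnosticReport", "DiagnosticReport.issued", primary = TRUE),
    m("report.interpretation_summary", "required", "DiagnosticReport",
      "DiagnosticReport.conclusion", primary = TRUE),
    ext("report.assessed_condition", "required", "DiagnosticReport",
        "DiagnosticReport.extension(diagnosticreport-assessedCondition)",
        extension_url = .ext_url("diagnosticreport-assessedCondition"), primary = TRUE),

    m("specimen.biomaterial_type", "required", "DiagnosticReport",
      "DiagnosticReport.specimen", "DiagnosticReport.specimen.display", primary = TRUE),
    m("specimen.specimen_id", "required", "DiagnosticReport",
      "DiagnosticReport.specimen", "DiagnosticReport.specimen.identifier", primary = TRUE),
    m("specimen.specimen_id", "required", "Observation",
      "Observation.specimen", "Observation.specimen.identifier"),
    ext("specimen.collection_date", "required", "DiagnosticReport",
        "DiagnosticReport.extension(diagnosticreport-specimenCollectionDate)",
        extension_url = .ext_url("diagnosticreport-specimenCollectionDate"),
        primary = TRUE),

    ext("genetic_variation.gene_hgnc_id", "required", "Observation",
        "Observation.extension(observation-geneticsGeneId)",
        extension_url = .ext_url("observation-geneticsGeneId"), primary = TRUE),
    ext("genetic_variation.gene_symbol", "required", "Observation",
        "Observation.extension(observation-geneticsGene)",
        extension_url = .ext_url("observation-geneticsGene"), primary = TRUE),
    ext("genetic_variation.variant_notation", "required", "Observation",
        "Observation.extension(observation-geneticsDNASequenceVariantName)",
        extension_url = .ext_url("observation-geneticsDNASequenceVariantName"),
        primary = TRUE),
    ext("genetic_variation.variant_effect", "required", "Observation",
        "Observation.extension(observation-geneticsDNASequenceVariantType)",
        extension_url = .ext_url("observation-geneticsDNASequenceVariantType"),
        primary = TRUE),
    ext("genetic_variation.variant_db_id", "required", "Observation",
        "Observation.extension(observation-geneticsDNAVariantId)",
        extension_url = .ext_url("observation-geneticsDNAVariantId"), primary = TRUE),
    ext("genetic_variation.classification", "required", "Observation",
        "Observation.extension(observation-classificationVariants).Tier",
        extension_url = paste0(.ext_url("observation-classificationVariants"), "#Tier"),
        component = "tier", primary = TRUE),
    ext("genetic_variation.classification", "required", "Observation",
        "Observation.extension(observation-classificationVariants).Pathogeny",
        extension_url = paste0(.ext_url("observation-classificationVariants"), "#Pathogeny"),
        component = "pathogeny"),
    ext("genetic_variation.classification", "required", "Observation",
        "Observation.extension(observation-classificationVariants).ClinicalRelavance",
        extension_url = paste0(.ext_url("observation-classificationVariants"), "#ClinicalRelavance"),
        component = "clinical_relevance"),
    m("genetic_variation.result_status", "required", "Observation", "Observation.status", primary = TRUE),
    m("genetic_variation.assay_code", "required", "Observation", "Observation.code", primary = TRUE),
    m("genetic_variation.observed_date", "required", "Observation", "Observation.effectiveDateTime", primary = TRUE),
    m("genetic_variation.test_method", "required", "Observation", "Observation.method", primary = TRUE),
    m("genetic_variation.interpretation", "required", "Observation", "Observation.interpretation", primary = TRUE),
    m("genetic_variation.comment", "required", "Observation", "Observation.comment", primary = TRUE),

    m("treatment.recommended_treatment", "required", "Medication", "Medication.code", primary = TRUE),
    ext("treatment.recommended_treatment", "required", "DiagnosticReport",
        "DiagnosticReport.extension(diagnosticreport-recommendedTreatment)",
        extension_url = .ext_url("diagnosticreport-recommendedTreatment"),
        component = "reference"),

    ## ---- optional field slots (49) ----
    m("research.condition_code", "optional", "Condition", "Condition.code", primary = TRUE),
    ext("research.study_id", "optional", "DiagnosticReport",
        "DiagnosticReport.extension(diagnosticreport-researchStudy)",
        extension_url = .ext_url("diagnosticreport-researchStudy"), primary = TRUE),
    ext("research.consent_status", "optional", "DiagnosticReport",
        "DiagnosticReport.extension(diagnosticreport-researchConsent)",
        extension_url = .ext_url("diagnosticreport-researchConsent"), primary = TRUE),
    m("research.coded_diagnosis", "optional", "DiagnosticReport",
      "DiagnosticReport.codedDiagnosis", primary = TRUE),
    m("research.report_category", "optional", "DiagnosticReport",
      "DiagnosticReport.category", primary = TRUE),

    m("research.sequence_type", "optional", "MolecularSequence", "MolecularSequence.type", primary = TRUE),
    m("research.coordinate_system", "optional", "MolecularSequence", "MolecularSequence.coordinateSystem", primary = TRUE),
    m("research.reference_assembly", "optional", "MolecularSequence", "MolecularSequence.referenceSeq.genomeBuild", primary = TRUE),
    m("research.chromosome", "optional", "MolecularSequence", "MolecularSequence.referenceSeq.chromosome", primary = TRUE),
    m("research.reference_seq_id", "optional", "MolecularSequence", "MolecularSequence.referenceSeq.referenceSeqId", primary = TRUE),
    m("research.strand", "optional", "MolecularSequence", "MolecularSequence.referenceSeq.strand", primary = TRUE),
    m("research.sequence_window", "optional", "MolecularSequence",
      "MolecularSequence.referenceSeq.windowStart", component = "start", primary = TRUE),
    m("research.sequence_window", "optional", "MolecularSequence",
      "MolecularSequence.referenceSeq.windowEnd", component = "end"),
    m("research.variant_position", "optional", "MolecularSequence",
      "MolecularSequence.variant.start", component = "start", primary = TRUE),
    m("research.variant_position", "optional", "MolecularSequence",
      "MolecularSequence.variant.end", component = "end"),
    m("research.observed_allele", "optional", "MolecularSequence", "MolecularSequence.variant.observedAllele", primary = TRUE),
    m("research.reference_allele", "optional", "MolecularSequence", "MolecularSequence.variant.referenceAllele", primary = TRUE),
    m("research.read_coverage", "optional", "MolecularSequence", "MolecularSequence.readCoverage", primary = TRUE),
    m("research.quality_score", "optional", "MolecularSequence", "MolecularSequence.quality.score", primary = TRUE),
    m("research.repository_pointer", "optional", "MolecularSequence",
      "MolecularSequence.repository.url", component = "url", primary = TRUE),
    m("research.repository_pointer", "optional", "MolecularSequence",
      "MolecularSequence.repository.name", component = "name"),

    ext("research.sequencing_platform", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-sequencingPlatform)",
        extension_url = .ext_url("molecularsequence-sequencingPlatform"), primary = TRUE),
    m("research.sequencing_platform", "optional", "Device", "Device.manufacturer",
      component = "manufacturer"),
    m("research.sequencing_platform", "optional", "Device", "Device.model",
      component = "model"),
    ext("research.analysis_platform", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-analysisPlatform)",
        extension_url = .ext_url("molecularsequence-analysisPlatform"), primary = TRUE),
    m("research.analysis_platform", "optional", "Device", "Device.version",
      component = "version"),
    ext("research.analysis_platform", "optional", "Device",
        "Device.extension(device-analysisPipeline)",
        extension_url = .ext_url("device-analysisPipeline"), component = "name"),
    ext("research.base_calling", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-baseCalling)",
        extension_url = .ext_url("molecularsequence-baseCalling"), primary = TRUE),
    ext("research.base_calling", "optional", "Device",
        "Device.extension(device-baseCallingAlgorithm)",
        extension_url = .ext_url("device-baseCallingAlgorithm")),
    ext("research.qc_metrics", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-qcMetrics).MeanDepth",
        extension_url = paste0(.ext_url("molecularsequence-qcMetrics"), "#MeanDepth"),
        component = "mean_depth", primary = TRUE),
    ext("research.qc_metrics", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-qcMetrics).TargetCoverage",
        extension_url = paste0(.ext_url("molecularsequence-qcMetrics"), "#TargetCoverage"),
        component = "target_coverage"),
    ext("research.qc_metrics", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-qcMetrics).Uniformity",
        extension_url = paste0(.ext_url("molecularsequence-qcMetrics"), "#Uniformity"),
        component = "uniformity"),
    ext("research.qc_metrics", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-qcMetrics).Q30Fraction",
        extension_url = paste0(.ext_url("molecularsequence-qcMetrics"), "#Q30Fraction"),
        component = "q30_fraction"),
    ext("research.qc_metrics", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-qcMetrics).TotalReads",
        extension_url = paste0(.ext_url("molecularsequence-qcMetrics"), "#TotalReads"),
        component = "total_reads"),
    ext("research.qc_metrics", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-qcMetrics).MappedFraction",
        extension_url = paste0(.ext_url("molecularsequence-qcMetrics"), "#MappedFraction"),
        component = "mapped_fraction"),
    ext("research.qc_metrics", "optional", "MolecularSequence",
        "MolecularSequence.extension(molecularsequence-qcMetrics).DuplicationRate",
        extension_url = paste0(.ext_url("molecularsequence-qcMetrics"), "#DuplicationRate"),
        component = "duplication_rate"),
    ext("research.flowcell_id", "optional", "Device",
        "Device.extension(device-flowcellId)",
        extension_url = .ext_url("device-flowcellId"), primary = TRUE),

    m("research.tumor_mutational_burden", "optional", "Observation",
      "Observation.component(tumorMutationalBurden)", primary = TRUE),
    ext("research.tumor_mutational_burden", "optional", "Observation",
        "Observation.extension(observation-tumorMutationalBurden)",
        extension_url = .ext_url("observation-tumorMutationalBurden")),
    m("research.microsatellite_status", "optional", "Observation",
      "Observation.component(microsatelliteStatus)", primary = TRUE),
    ext("research.microsatellite_status", "optional", "Observation",
        "Observation.extension(observation-microsatelliteStatus)",
        extension_url = .ext_url("observation-microsatelliteStatus")),
    m("research.tumor_purity", "optional", "Observation",
      "Observation.component(tumorPurity)", primary = TRUE),
    ext("research.tumor_purity", "optional", "Observation",
        "Observation.extension(observation-tumorPurity)",
        extension_url = .ext_url("observation-tumorPurity")),
    m("research.hrd_score", "optional", "Observation",
      "Observation.component(hrdScore)", primary = TRUE),
    ext("research.hrd_score", "optional", "Observation",
        "Observation.extension(observation-hrdScore)",
        extension_url = .ext_url("observation-hrdScore")),
    m("research.mutational_signature", "optional", "Observation",
      "Observation.component(mutationalSignature)", primary = TRUE),
    ext("research.mutational_signature", "optional", "Observation",
        "Observation.extension(observation-mutationalSignature)",
        extension_url = .ext_url("observation-mutationalSignature")),
    m("research.circulating_dna_fraction", "optional", "Observation",
      "Observation.component(circulatingDnaFraction)", primary = TRUE),
    ext("research.circulating_dna_fraction", "optional", "Observation",
        "Observation.extension(observation-circulatingDnaFraction)",
        extension_url = .ext_url("observation-circulatingDnaFraction"))
  )
  do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Load the element-to-FHIR mapping table
#'
#' One row per mapped FHIR slot (see the package vignette for the
#' element-versus-slot accounting). \code{element_id} is non-unique: composite
#' elements expand into sub-extension slots and some elements are surfaced on
#' more than one resource.
#'
#' @return A data frame with columns \code{element_id}, \code{field_class},
#'   \code{resource_type}, \code{fhir_path} (display dialect),
#'   \code{structural_path}, \code{mapping_kind} ("reuse"/"extension"),
#'   \code{extension_url}, \code{component}, \code{primary}.
#' @export
load_mapping_table <- function() {
  if (is.null(.seqreport_env$mapping)) {
    .seqreport_env$mapping <- .mapping_rows()
  }
  .seqreport_env$mapping
}

#' Map one element to its primary FHIR target
#'
#' Returns the element's primary slot: the mapping row whose path is the
#' canonical storage location of the element's (whole or first-component)
#' value. All slots for an element are available from [element_slots()].
#'
#' @param element_id Registry element key.
#' @return A one-row data frame from the mapping table.
#' @examples
#' map_element("genetic_variation.gene_symbol")$fhir_path
#' @export
map_element <- function(element_id) {
  element_lookup(element_id)  # errors on unknown ids with nearest matches
  map <- load_mapping_table()
  hit <- map[map$element_id == element_id & map$primary, , drop = FALSE]
  hit[1, , drop = FALSE]
}

#' All mapping slots for one element
#' @param element_id Registry element key.
#' @return Data frame of all mapping rows for the element.
#' @export
element_slots <- function(element_id) {
  element_lookup(element_id)
  map <- load_mapping_table()
  map[map$element_id == element_id, , drop = FALSE]
}

.RESOURCES_REQUIRED <- c("ProcedureRequest", "DiagnosticReport", "Observation",
                         "Medication", "Patient")
.RESOURCES_OPTIONAL <- c("Condition", "DiagnosticReport", "MolecularSequence",
                         "Observation", "Device")

#' Per-resource mapping statistics
#'
#' Counts, for each field class and target resource type, the number of reused
#' core-element slots and extension slots in the mapping table, with field-class
#' totals and the grand total. Computed by counting rows, never stored.
#'
#' @param mapping A mapping table (defaults to the shipped table; pass a
#'   filtered table to audit a subset).
#' @return A list with data frames \code{required} and \code{optional}
#'   (columns \code{resource_type}, \code{elements}, \code{extensions}; final
#'   row \code{"Total"}) and \code{grand_total} (all slots).
#' @export
mapping_statistics <- function(mapping = load_mapping_table()) {
  count_block <- function(fc, resources) {
    sub <- mapping[mapping$field_class == fc, , drop = FALSE]
    rows <- lapply(resources, function(rt) {
      at <- sub[sub$resource_type == rt, , drop = FALSE]
      data.frame(resource_type = rt,
                 elements = sum(at$mapping_kind == "reuse"),
                 extensions = sum(at$mapping_kind == "extension"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rbind(out, data.frame(resource_type = "Total",
                          elements = sum(out$elements),
                          extensions = sum(out$extensions),
                          stringsAsFactors = FALSE))
  }
  req <- count_block("required", .RESOURCES_REQUIRED)
  opt <- count_block("optional", .RESOURCES_OPTIONAL)
  list(required = req, optional = opt,
       grand_total = sum(req$elements[req$resource_type == "Total"],
                         req$extensions[req$resource_type == "Total"],
                         opt$elements[opt$resource_type == "Total"],
                         opt$extensions[opt$resource_type == "Total"]))
}

.extension_defs <- function() {
  d <- function(name, value_type, host) {
    url <- if (grepl("\\.", name)) {
      parts <- strsplit(name, ".", fixed = TRUE)[[1]]
      paste0(.ext_url(parts[1]), "#", parts[2])
    } else .ext_url(name)
    list(name = name, url = url, value_type = value_type, host_resource = host)
  }
  rows <- list(
    d("patient-sexIso22220", "code", "Patient"),
    d("patient-ethnicity", "code", "Patient"),
    d("diagnosticreport-legallyAuthorizedRepresentative", "string", "DiagnosticReport"),
    d("diagnosticreport-assessedCondition", "string", "DiagnosticReport"),
    d("diagnosticreport-specimenCollectionDate", "string", "DiagnosticReport"),
    d("diagnosticreport-recommendedTreatment", "identifier", "DiagnosticReport"),
    d("diagnosticreport-researchStudy", "identifier", "DiagnosticReport"),
    d("diagnosticreport-researchConsent", "code", "DiagnosticReport"),
    d("observation-geneticsGeneId", "identifier", "Observation"),
    d("observation-geneticsGene", "string", "Observation"),
    d("observation-geneticsDNASequenceVariantName", "string", "Observation"),
    d("observation-geneticsDNASequenceVariantType", "string", "Observation"),
    d("observation-geneticsDNAVariantId", "identifier", "Observation"),
    d("observation-classificationVariants", "codeable-concept", "Observation"),
    d("observation-classificationVariants.Tier", "code", "Observation"),
    d("observation-classificationVariants.Pathogeny", "code", "Observation"),
    d("observation-classificationVariants.ClinicalRelavance", "code", "Observation"),
    d("molecularsequence-sequencingPlatform", "string", "MolecularSequence"),
    d("molecularsequence-analysisPlatform", "string", "MolecularSequence"),
    d("molecularsequence-baseCalling", "string", "MolecularSequence"),
    d("molecularsequence-qcMetrics", "quantity", "MolecularSequence"),
    d("molecularsequence-qcMetrics.MeanDepth", "quantity", "MolecularSequence"),
    d("molecularsequence-qcMetrics.TargetCoverage", "quantity", "MolecularSequence"),
    d("molecularsequence-qcMetrics.Uniformity", "quantity", "MolecularSequence"),
    d("molecularsequence-qcMetrics.Q30Fraction", "quantity", "MolecularSequence"),
    d("molecularsequence-qcMetrics.TotalReads", "quantity", "MolecularSequence"),
    d("molecularsequence-qcMetrics.MappedFraction", "quantity", "MolecularSequence"),
    d("molecularsequence-qcMetrics.DuplicationRate", "quantity", "MolecularSequence"),
    d("device-analysisPipeline", "string", "Device"),
    d("device-baseCallingAlgorithm", "string", "Device"),
    d("device-flowcellId", "identifier", "Device"),
    d("observation-tumorMutationalBurden", "quantity", "Observation"),
    d("observation-microsatelliteStatus", "code", "Observation"),
    d("observation-tumorPurity", "quantity", "Observation"),
    d("observation-hrdScore", "quantity", "Observation"),
    d("observation-mutationalSignature", "string", "Observation"),
    d("observation-circulatingDnaFraction", "quantity", "Observation")
  )
  do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Registered extension definitions
#'
#' All extension definitions referenced by the mapping table, including the
#' three classification sub-extensions (Tier, Pathogeny, ClinicalRelavance —
#' the last spelled as in the source profile set) and the genetics extensions
#' of the variant Observation. Sub-extensions of a complex extension carry a
#' dotted name and a \code{#fragment} URL under the parent's URL.
#'
#' @return Data frame with columns \code{name}, \code{url}, \code{value_type},
#'   \code{host_resource}.
#' @export
extension_definitions <- function() .extension_defs()

#' Export / import the mapping table
#'
#' Export writes the table with byte-stable ordering (field_class,
#' resource_type, element_id); import reads it back losslessly.
#'
#' @param path File path; format by extension (.csv or .json).
#' @return `export_mapping_table` the path invisibly; `import_mapping_table`
#'   the mapping data frame.
#' @export
export_mapping_table <- function(path) {
  map <- load_mapping_table()
  map <- map[order(map$field_class, map$resource_type, map$element_id), ]
  rownames(map) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(map, path, dataframe = "rows", pretty = TRUE, na = "null")
  } else {
    utils::write.csv(map, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname export_mapping_table
#' @export
import_mapping_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    map <- jsonlite::fromJSON(path)
    map$component[sapply(map$component, is.null)] <- NA_character_
    map <- as.data.frame(lapply(map, unlist), stringsAsFactors = FALSE)
  } else {
    map <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(component = "character"))
    map$component[!nzchar(map$component) | is.na(map$component)] <- NA_character_
    map$extension_url[is.na(map$extension_url)] <- ""
  }
  map$primary <- as.logical(map$primary)
  map
}
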