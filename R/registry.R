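# Element registry for the structured clinical genomic sequencing report
# (ISO/TS 20428 dialect): 32 required + 29 optional data elements, each with a
# terminology/format binding. Elements whose name and binding are printed in the
# source standard's published mapping example carry provenance "paper"; elements
# reconstructed here (the full element list is not publicly enumerable) carry
# provenance "reconstructed".

.seqreport_env <- new.env(parent = emptyenv())

# section labels
.SEC_ORDER <- "Clinical sequencing order"
.SEC_SUBJECT <- "Information on subject of care"
.SEC_PERFORMER <- "Order authorization and performer"
.SEC_REPORT <- "Clinical sequencing report"
.SEC_SPECIMEN <- "Biomaterial information"
.SEC_VARIATION <- "Genetic variation"
.SEC_TREATMENT <- "Recommended treatments"
.SEC_RESEARCH <- "Clinical research information"
.SEC_SEQDETAIL <- "Sequencing detail"
.SEC_BIOMARKER <- "Genomic biomarkers"

.registry_rows <- function() {
  r <- function(id, name, class, section, standard, prov) {
    list(element_id = id, display_name = name, field_class = class,
         section = section, metadata_standard = standard, provenance = prov)
  }
  rows <- list(
    ## --- required (32) ---
    r("order.order_id", "Order identifier", "required", .SEC_ORDER, "text", "reconstructed"),
    r("order.order_date", "Order date", "required", .SEC_ORDER, "ISO 8601", "reconstructed"),
    r("order.ordering_clinician", "Ordering clinician", "required", .SEC_ORDER, "text", "reconstructed"),
    r("subject.identifier", "Identifiers", "required", .SEC_SUBJECT, "ISO/TS 22220:2011", "paper"),
    r("subject.name", "Name", "required", .SEC_SUBJECT, "ISO/TS 22220:2011", "paper"),
    r("subject.birth_date", "Birth date", "required", .SEC_SUBJECT, "ISO 8601", "paper"),
    r("subject.sex", "Sex", "required", .SEC_SUBJECT, "ISO/TS 22220:2011", "paper"),
    r("subject.ethnicity", "Ethnicity", "required", .SEC_SUBJECT, "HL7 v3 race", "paper"),
    r("order.legally_authorized_person", "Legally authorized person", "required", .SEC_PERFORMER, "text", "paper"),
    r("order.performing_laboratory", "Performing laboratory", "required", .SEC_PERFORMER, "text", "paper"),
    r("report.report_id", "Report identifier", "required", .SEC_REPORT, "text", "reconstructed"),
    r("report.status", "Report status", "required", .SEC_REPORT, "text", "reconstructed"),
    r("report.test_code", "Test code", "required", .SEC_REPORT, "text", "reconstructed"),
    r("report.issued_date", "Report issued date", "required", .SEC_REPORT, "ISO 8601", "reconstructed"),
    r("report.interpretation_summary", "Interpretation summary", "required", .SEC_REPORT, "text", "paper"),
    r("report.assessed_condition", "Assessed condition", "required", .SEC_REPORT, "text", "reconstructed"),
    r("specimen.biomaterial_type", "Biomaterial type", "required", .SEC_SPECIMEN, "text", "paper"),
    r("specimen.specimen_id", "Specimen identifier", "required", .SEC_SPECIMEN, "text", "reconstructed"),
    r("specimen.collection_date", "Specimen collection date", "required", .SEC_SPECIMEN, "ISO 8601", "reconstructed"),
    r("genetic_variation.gene_hgnc_id", "Gene HGNC identifier", "required", .SEC_VARIATION, "HGNC", "paper"),
    r("genetic_variation.gene_symbol", "Gene symbols and names", "required", .SEC_VARIATION, "HGNC", "paper"),
    r("genetic_variation.variant_notation", "Notation", "required", .SEC_VARIATION, "HGVS", "paper"),
    r("genetic_variation.variant_effect", "Effects of variants", "required", .SEC_VARIATION, "text", "paper"),
    r("genetic_variation.variant_db_id", "Sequence variant ID", "required", .SEC_VARIATION, "database-ID", "paper"),
    r("genetic_variation.classification", "Variant classification", "required", .SEC_VARIATION, "text", "paper"),
    r("genetic_variation.result_status", "Variant result status", "required", .SEC_VARIATION, "text", "reconstructed"),
    r("genetic_variation.assay_code", "Variant assay code", "required", .SEC_VARIATION, "text", "reconstructed"),
    r("genetic_variation.observed_date", "Variant observed date", "required", .SEC_VARIATION, "ISO 8601", "reconstructed"),
    r("genetic_variation.test_method", "Test method", "required", .SEC_VARIATION, "text", "reconstructed"),
    r("genetic_variation.interpretation", "Variant interpretation", "required", .SEC_VARIATION, "text", "reconstructed"),
    r("genetic_variation.comment", "Variant comment", "required", .SEC_VARIATION, "text", "reconstructed"),
    r("treatment.recommended_treatment", "Recommended treatments", "required", .SEC_TREATMENT, "text", "paper"),
    ## --- optional (29) ---
    r("research.condition_code", "Research condition", "optional", .SEC_RESEARCH, "text", "reconstructed"),
    r("research.study_id", "Research study identifier", "optional", .SEC_RESEARCH, "text", "reconstructed"),
    r("research.consent_status", "Research consent status", "optional", .SEC_RESEARCH, "text", "reconstructed"),
    r("research.coded_diagnosis", "Coded diagnosis", "optional", .SEC_RESEARCH, "text", "reconstructed"),
    r("research.report_category", "Report category", "optional", .SEC_RESEARCH, "text", "reconstructed"),
    r("research.sequence_type", "Sequence type", "optional", .SEC_SEQDETAIL, "text", "reconstructed"),
    r("research.coordinate_system", "Coordinate system", "optional", .SEC_SEQDETAIL, "text", "reconstructed"),
    r("research.reference_assembly", "Reference assembly", "optional", .SEC_SEQDETAIL, "text", "reconstructed"),
    r("research.chromosome", "Chromosome", "optional", .SEC_SEQDETAIL, "text", "reconstructed"),
    r("research.reference_seq_id", "Reference sequence ID", "optional", .SEC_SEQDETAIL, "database-ID", "reconstructed"),
    r("research.strand", "Strand", "optional", .SEC_SEQDETAIL, "text", "reconstructed"),
    r("research.sequence_window", "Sequence window", "optional", .SEC_SEQDETAIL, "none", "reconstructed"),
    r("research.variant_position", "Variant position", "optional", .SEC_SEQDETAIL, "none", "reconstructed"),
    r("research.observed_allele", "Observed allele", "optional", .SEC_SEQDETAIL, "text", "reconstructed"),
    r("research.reference_allele", "Reference allele", "optional", .SEC_SEQDETAIL, "text", "reconstructed"),
    r("research.read_coverage", "Read coverage", "optional", .SEC_SEQDETAIL, "none", "reconstructed"),
    r("research.quality_score", "Quality score", "optional", .SEC_SEQDETAIL, "none", "reconstructed"),
    r("research.repository_pointer", "Sequence repository", "optional", .SEC_SEQDETAIL, "none", "reconstructed"),
    r("research.sequencing_platform", "Sequencing platform", "optional", .SEC_SEQDETAIL, "text", "paper"),
    r("research.analysis_platform", "Analysis platform", "optional", .SEC_SEQDETAIL, "text", "paper"),
    r("research.base_calling", "Base calling", "optional", .SEC_SEQDETAIL, "text", "paper"),
    r("research.qc_metrics", "Quality control metrics", "optional", .SEC_SEQDETAIL, "none", "paper"),
    r("research.flowcell_id", "Flow cell identifier", "optional", .SEC_SEQDETAIL, "text", "reconstructed"),
    r("research.tumor_mutational_burden", "Tumor mutational burden", "optional", .SEC_BIOMARKER, "none", "reconstructed"),
    r("research.microsatellite_status", "Microsatellite status", "optional", .SEC_BIOMARKER, "text", "reconstructed"),
    r("research.tumor_purity", "Tumor purity", "optional", .SEC_BIOMARKER, "none", "reconstructed"),
    r("research.hrd_score", "Homologous recombination deficiency score", "optional", .SEC_BIOMARKER, "none", "reconstructed"),
    r("research.mutational_signature", "Dominant mutational signature", "optional", .SEC_BIOMARKER, "text", "reconstructed"),
    r("research.circulating_dna_fraction", "Circulating tumor DNA fraction", "optional", .SEC_BIOMARKER, "none", "reconstructed")
  )
  do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Load the report data-element registry
#'
#' Returns the full registry of structured sequencing-report data elements:
#' 32 required elements (clinical use) and 29 optional elements (research use),
#' each with a section label, a terminology or format binding
#' (\code{metadata_standard}), and a provenance flag. The registry is embedded
#' data; loading is idempotent and the row order is stable.
#'
#' @return A data frame with columns \code{element_id}, \code{display_name},
#'   \code{field_class} ("required"/"optional"), \code{section},
#'   \code{metadata_standard}, \code{provenance} ("paper"/"reconstructed").
#' @examples
#' reg <- load_element_registry()
#' table(reg$field_class)
#' @export
load_element_registry <- function() {
  if (is.null(.seqreport_env$registry)) {
    reg <- .registry_rows()
    dup <- reg$element_id[duplicated(reg$element_id)]
    if (length(dup) > 0) {
      stop("element registry corrupt: duplicated element_id(s): ",
           paste(unique(dup), collapse = ", "))
    }
    .seqreport_env$registry <- reg
  }
  .seqreport_env$registry
}

#' Look up one registry element by id
#'
#' @param element_id Dot-path element key, e.g. \code{"subject.birth_date"}.
#' @return A one-row data frame (the element's registry record).
#' @examples
#' element_lookup("subject.birth_date")$metadata_standard
#' @export
element_lookup <- function(element_id) {
  reg <- load_element_registry()
  hit <- reg[reg$element_id == element_id, , drop = FALSE]
  if (nrow(hit) == 0) {
    near <- utils::head(reg$element_id[order(utils::adist(reg$element_id, element_id))], 3)
    stop("unknown element_id '", element_id, "'; nearest matches: ",
         paste(near, collapse = ", "))
  }
  hit
}

.value_sets <- function() {
  list(
    pathogeny = data.frame(
      code = c("Pathogenic", "Likely pathogenic", "Unknown significance",
               "Likely benign", "Benign"),
      display = c("Pathogenic", "Likely pathogenic", "Unknown significance",
                  "Likely benign", "Benign"),
      stringsAsFactors = FALSE),
    clinical_relevance = data.frame(
      code = c("Identified", "Likely identified", "Uncertain", "Not identified"),
      display = c("Identified", "Likely identified", "Uncertain", "Not identified"),
      stringsAsFactors = FALSE),
    # "1" = Male is fixed by the standard's worked example; the remaining codes
    # follow the conventional sex-at-registration code table.
    sex_iso22220 = data.frame(
      code = c("1", "2", "0", "9"),
      display = c("Male", "Female", "Not known", "Not specified"),
      stringsAsFactors = FALSE),
    # open 4-tier somatic classification; accepted tiers are configurable in
    # principle but ship as Tier 1..Tier 4
    tier = data.frame(
      code = paste("Tier", 1:4),
      display = paste("Tier", 1:4),
      stringsAsFactors = FALSE),
    # bundled micro-valueset of HL7 v3 race/ethnicity codes used in examples;
    # lexical validation ("<digits>-<digit>") is the primary check
    race_hl7v3 = data.frame(
      code = c("2040-4", "2028-9", "2106-3", "2054-5", "2076-8"),
      display = c("Korean", "Asian", "White", "Black or African American",
                  "Native Hawaiian or Other Pacific Islander"),
      stringsAsFactors = FALSE)
  )
}

#' Retrieve a controlled value set
#'
#' @param name Value-set key: one of \code{"pathogeny"},
#'   \code{"clinical_relevance"}, \code{"sex_iso22220"}, \code{"tier"},
#'   \code{"race_hl7v3"}.
#' @return A data frame with columns \code{code} and \code{display}, in
#'   defined order.
#' @examples
#' value_set("pathogeny")$code
#' @export
value_set <- function(name) {
  vs <- .value_sets()
  if (!name %in% names(vs)) {
    stop("unknown value set '", name, "'; registered sets: ",
         paste(names(vs), collapse = ", "))
  }
  vs[[name]]
}

#' Export the element registry to CSV or JSON
#'
#' @param path Output file path.
#' @param format "csv" or "json" (default inferred from the file extension).
#' @return The path, invisibly.
#' @export
export_registry <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  reg <- load_element_registry()
  if (format == "csv") {
    utils::write.csv(reg, path, row.names = FALSE)
  } else {
    jsonlite::write_json(reg, path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
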