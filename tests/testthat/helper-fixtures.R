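# Shared fixtures and the independent field-placement oracle.

# Published per-resource slot counts (reused elements, extension elements)
PUBLISHED_REQUIRED_COUNTS <- data.frame(
  resource_type = c("ProcedureRequest", "DiagnosticReport", "Observation",
                    "Medication", "Patient"),
  elements = c(3, 12, 8, 1, 2),
  extensions = c(0, 5, 8, 0, 2),
  stringsAsFactors = FALSE)
PUBLISHED_OPTIONAL_COUNTS <- data.frame(
  resource_type = c("Condition", "DiagnosticReport", "MolecularSequence",
                    "Observation", "Device"),
  elements = c(1, 2, 16, 6, 3),
  extensions = c(0, 2, 10, 6, 3),
  stringsAsFactors = FALSE)

# Fully populated synthetic report (all optional fields present).
full_report <- function(seed = 101) {
  cfg <- generator_config(seed = seed, n_reports = 1,
                          include_research_block = 1, missingness = 0)
  generate_reports(cfg)[[1]]
}

# Independent field-placement oracle: for every populated element, walking the
# bundle at each mapping slot's structural path must recover the corresponding
# (component of the) report value. Returns a character vector of mismatches.
check_field_placement <- function(report, bundle) {
  problems <- character(0)
  note <- function(id, what) problems <<- c(problems, paste0(id, ": ", what))
  eq <- function(a, b) isTRUE(all.equal(a, b, check.attributes = FALSE))

  reg <- load_element_registry()
  for (id in reg$element_id) {
    value <- report_element_value(report, id)
    if (is.null(value)) next
    rows <- element_slots(id)
    if (startsWith(id, "genetic_variation.")) {
      if (length(value) == 0) next
      if (id == "genetic_variation.classification") {
        for (i in seq_len(nrow(rows))) {
          walked <- walk_bundle_path(bundle, rows$structural_path[i])
          expected <- lapply(value, `[[`, rows$component[i])
          if (!eq(sort(unlist(walked)), sort(unlist(expected)))) {
            note(id, rows$structural_path[i])
          }
        }
      } else {
        walked <- walk_bundle_path(bundle, rows$structural_path[rows$primary])
        if (!eq(sort(unlist(walked)), sort(unlist(value)))) note(id, "primary slot")
      }
    } else if (id == "treatment.recommended_treatment") {
      walked <- walk_bundle_path(bundle, "Medication.code")
      if (!eq(sort(unlist(walked)), sort(unlist(value)))) note(id, "Medication.code")
      refs <- walk_bundle_path(
        bundle, rows$structural_path[rows$mapping_kind == "extension"])
      if (length(refs) != length(value)) note(id, "treatment reference count")
      for (ref in refs) {
        med <- resolve_reference(bundle, ref$reference)
        if (is.null(med) || !med$body$code %in% unlist(value)) {
          note(id, "treatment reference target")
        }
      }
    } else {
      for (i in seq_len(nrow(rows))) {
        comp <- rows$component[i]
        expected <- if (is.na(comp)) value else value[[comp]]
        if (is.null(expected)) next
        walked <- walk_bundle_path(bundle, rows$structural_path[i])
        if (length(walked) == 0) { note(id, paste0("empty at ", rows$structural_path[i])); next }
        for (w in walked) if (!eq(w, expected)) note(id, rows$structural_path[i])
      }
    }
  }
  problems
}

# Minimal well-formed VCF writer for shim tests.
write_toy_vcf <- function(path, records) {
  header <- c("##fileformat=VCFv4.2",
              "##source=seqreport-test",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  writeLines(c(header, records), path)
  path
}
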