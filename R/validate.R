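# Conformance checking against the element registry, terminology bindings and
# value sets. Findings are returned as a data frame of issues, never thrown:
# error severity marks required-field or format/code violations that make the
# report non-conformant (and block bundle building); warning severity marks
# advisory findings. Optional-field absence is never an issue.

.issue <- function(severity, element_id, code, message) {
  data.frame(severity = severity, element_id = element_id, code = code,
             message = message, stringsAsFactors = FALSE)
}

.no_issues <- function() {
  data.frame(severity = character(0), element_id = character(0),
             code = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

.is_iso_date <- function(x) {
  is.character(x) && grepl("^\\d{4}-\\d{2}-\\d{2}$", x) &&
    !is.na(suppressWarnings(as.Date(x, format = "%Y-%m-%d")))
}

# advisory vocabulary for the free-text variant-effect field
.EFFECT_SUGGESTIONS <- c("Substitution (missense)", "Substitution (nonsense)",
                         "Substitution (silent)", "Deletion", "Insertion",
                         "Duplication", "Frameshift", "Splice site")

#' Check one code against a terminology/format binding
#'
#' Pattern and value-set checks for the registry's metadata standards: HGNC
#' ids must match \code{HGNC:<digits>}; dates must parse as ISO 8601
#' (YYYY-MM-DD); sex codes must belong to the ISO/TS 22220 code table; race
#' codes must match the HL7 v3 lexical shape \code{<digits>-<digit>}; HGVS
#' strings must parse in the report dialect; \code{text}/\code{none} accept
#' any non-empty string.
#'
#' @param system Binding label (registry \code{metadata_standard}) or value-set
#'   name ("pathogeny", "clinical_relevance", "tier").
#' @param code The code/value to check.
#' @param element_id Element id used in the returned issue (default the system).
#' @return TRUE when the code conforms, otherwise a one-row issue data frame.
#' @export
validate_code <- function(system, code, element_id = system) {
  ok <- TRUE
  bad <- function(code_, msg) .issue("error", element_id, code_, msg)
  if (system == "HGNC") {
    if (!grepl("^HGNC:[0-9]+$", code %||% "")) {
      return(bad("bad-format", paste0("'", code, "' does not match HGNC:<digits>")))
    }
  } else if (system == "ISO 8601") {
    if (!.is_iso_date(code)) {
      return(bad("bad-format", paste0("'", code, "' is not an ISO 8601 date (YYYY-MM-DD)")))
    }
  } else if (system == "ISO/TS 22220:2011") {
    # of the identification fields, only the sex code table is enumerable
    if (element_id == "subject.sex" && !code %in% value_set("sex_iso22220")$code) {
      return(bad("bad-code", paste0("sex code '", code, "' not in value set sex_iso22220")))
    }
  } else if (system == "HL7 v3 race") {
    if (!grepl("^[0-9]+-[0-9]$", code %||% "")) {
      return(bad("bad-format", paste0("'", code, "' does not match the HL7 v3 race code shape <digits>-<digit>")))
    }
  } else if (system == "HGVS") {
    res <- tryCatch({ parse_variant_notation(code); TRUE },
                    error = function(e) conditionMessage(e))
    if (!isTRUE(res)) return(bad("bad-format", res))
  } else if (system %in% c("pathogeny", "clinical_relevance", "tier")) {
    if (!code %in% value_set(system)$code) {
      return(bad("bad-code", paste0("'", code, "' not in value set ", system)))
    }
  } else if (system %in% c("text", "none", "database-ID")) {
    if (!is.null(code) && is.character(code) && !nzchar(code)) {
      return(bad("bad-format", "empty string"))
    }
  } else {
    stop("unknown binding system '", system, "'")
  }
  ok
}

.populated <- function(x) {
  if (is.null(x)) return(FALSE)
  if (is.list(x)) return(length(x) > 0)
  if (is.character(x)) return(any(nzchar(x)))
  TRUE
}

.check_variant <- function(v, idx) {
  issues <- .no_issues()
  pre <- function(id) paste0(id, "[", idx, "]")
  if (.populated(v$gene_hgnc_id)) {
    r <- validate_code("HGNC", v$gene_hgnc_id, "genetic_variation.gene_hgnc_id")
    if (!isTRUE(r)) issues <- rbind(issues, r)
  }
  if (.populated(v$hgvs_notation)) {
    r <- validate_code("HGVS", v$hgvs_notation, "genetic_variation.variant_notation")
    if (!isTRUE(r)) issues <- rbind(issues, r)
  }
  if (.populated(v$observed_date)) {
    r <- validate_code("ISO 8601", v$observed_date, "genetic_variation.observed_date")
    if (!isTRUE(r)) issues <- rbind(issues, r)
  }
  if (!is.null(v$classification)) {
    cl <- v$classification
    for (p in list(c("tier", cl$tier), c("pathogeny", cl$pathogeny),
                   c("clinical_relevance", cl$clinical_relevance))) {
      r <- validate_code(p[1], p[2], "genetic_variation.classification")
      if (!isTRUE(r)) issues <- rbind(issues, r)
    }
  }
  if (.populated(v$variant_effect) && !v$variant_effect %in% .EFFECT_SUGGESTIONS) {
    issues <- rbind(issues, .issue(
      "warning", "genetic_variation.variant_effect", "bad-code",
      paste0("effect '", v$variant_effect,
             "' is free text; suggested terms: ",
             paste(utils::head(.EFFECT_SUGGESTIONS, 3), collapse = ", "), ", ...")))
  }
  issues
}

#' Validate a sequencing report against the element registry
#'
#' Emits one \code{missing-required} issue per absent required element (the
#' variant-section elements are checked per variant; an explicitly empty
#' variant list is a conformant no-reportable-variants statement, an absent
#' one is not), and code/format issues for populated fields. An empty result
#' means the report is conformant and buildable.
#'
#' @param report A \code{sequencing_report}.
#' @return Data frame of issues (zero rows when conformant) with columns
#'   \code{severity}, \code{element_id}, \code{code}, \code{message}.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "sequencing_report"))
  reg <- load_element_registry()
  issues <- .no_issues()
  required <- reg$element_id[reg$field_class == "required"]
  variant_ids <- names(.VARIANT_FIELD_MAP)

  for (id in required) {
    if (id %in% variant_ids) {
      if (is.null(report$variants)) {
        issues <- rbind(issues, .issue("error", id, "missing-required",
                                       "variant section absent"))
      } else if (length(report$variants) > 0) {
        vals <- report_element_value(report, id)
        if (any(!vapply(vals, .populated, logical(1)))) {
          issues <- rbind(issues, .issue("error", id, "missing-required",
                                         "absent in at least one variant"))
        }
      }
    } else {
      val <- report_element_value(report, id)
      if (!.populated(val)) {
        issues <- rbind(issues, .issue("error", id, "missing-required",
                                       "required element not populated"))
      }
    }
  }

  # format / code checks on populated fields
  scalar_checks <- list(
    c("subject.birth_date", "ISO 8601"),
    c("subject.sex", "ISO/TS 22220:2011"),
    c("subject.ethnicity", "HL7 v3 race"),
    c("order.order_date", "ISO 8601"),
    c("report.issued_date", "ISO 8601"),
    c("specimen.collection_date", "ISO 8601"))
  for (chk in scalar_checks) {
    val <- report_element_value(report, chk[1])
    if (.populated(val)) {
      r <- validate_code(chk[2], val, chk[1])
      if (!isTRUE(r)) issues <- rbind(issues, r)
    }
  }
  if (!is.null(report$variants) && length(report$variants) > 0) {
    for (i in seq_along(report$variants)) {
      issues <- rbind(issues, .check_variant(report$variants[[i]], i))
    }
  }
  rownames(issues) <- NULL
  issues
}

#' Bundle coverage audit in the shape of the mapping statistics
#'
#' Counts, per field class and resource type, the mapping-table slots whose
#' structural path resolves to a populated value in the bundle. A bundle built
#' from a fully populated report reproduces the mapping statistics exactly;
#' an empty bundle yields all zeros.
#'
#' @param bundle A \code{fhir_bundle}.
#' @return Same structure as [mapping_statistics()].
#' @export
coverage_summary <- function(bundle) {
  map <- load_mapping_table()
  populated <- vapply(seq_len(nrow(map)), function(i) {
    length(walk_bundle_path(bundle, map$structural_path[i])) > 0
  }, logical(1))
  mapping_statistics(map[populated, , drop = FALSE])
}
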