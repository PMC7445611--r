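# The structured sequencing-report document model and its composite-field
# grammars. Constructors are deliberately permissive: conformance (required
# completeness, value-set membership, format bindings) is the validation
# module's job, so that non-conformant fixtures can be represented.

#' Variant classification triple
#'
#' The clinical classification of a somatic variant, decomposed into a tier,
#' a pathogenicity code (5-code value set) and a clinical-relevance code
#' (4-code value set). The printed form is
#' \code{"<Tier> (<Pathogeny>, <ClinicalRelevance>)"}.
#'
#' @param tier Tier code ("Tier 1" .. "Tier 4").
#' @param pathogeny Code from [value_set()] "pathogeny".
#' @param clinical_relevance Code from value set "clinical_relevance".
#' @param validate Check codes against their value sets (default TRUE).
#' @return Object of class \code{classification_triple}.
#' @export
classification_triple <- function(tier, pathogeny, clinical_relevance,
                                  validate = TRUE) {
  if (validate) {
    if (!tier %in% value_set("tier")$code)
      stop("invalid tier code '", tier, "'")
    if (!pathogeny %in% value_set("pathogeny")$code)
      stop("invalid pathogeny code '", pathogeny, "'")
    if (!clinical_relevance %in% value_set("clinical_relevance")$code)
      stop("invalid clinical_relevance code '", clinical_relevance, "'")
  }
  structure(list(tier = tier, pathogeny = pathogeny,
                 clinical_relevance = clinical_relevance),
            class = "classification_triple")
}

#' Parse the printed classification form
#'
#' Splits \code{"<Tier> (<Pathogeny>, <ClinicalRelevance>)"} (for example
#' \code{"Tier 1 (Pathogenic, Identified)"}) into a [classification_triple()].
#' Whitespace-tolerant; each component is validated against its value set.
#'
#' @param text Classification string.
#' @return A \code{classification_triple}.
#' @export
parse_classification <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*(Tier\\s*[0-9]+)\\s*\\(\\s*([^,()]+?)\\s*,\\s*([^,()]+?)\\s*\\)\\s*$",
    text))[[1]]
  if (length(m) != 4) {
    stop("cannot parse classification '", text,
         "': expected \"<Tier> (<Pathogeny>, <ClinicalRelevance>)\"")
  }
  tier <- sub("^Tier\\s*", "Tier ", m[2])
  if (!tier %in% value_set("tier")$code)
    stop("classification tier component out of value set: '", tier, "'")
  if (!m[3] %in% value_set("pathogeny")$code)
    stop("classification pathogeny component out of value set: '", m[3], "'")
  if (!m[4] %in% value_set("clinical_relevance")$code)
    stop("classification clinical-relevance component out of value set: '", m[4], "'")
  classification_triple(tier, m[3], m[4])
}

#' Format a classification triple to its canonical printed form
#'
#' Inverse of [parse_classification()] on valid triples.
#'
#' @param triple A \code{classification_triple}.
#' @return String \code{"<Tier> (<Pathogeny>, <ClinicalRelevance>)"}.
#' @export
format_classification <- function(triple) {
  stopifnot(inherits(triple, "classification_triple"))
  # re-validate: triples constructed with validate = FALSE may carry bad codes
  classification_triple(triple$tier, triple$pathogeny, triple$clinical_relevance)
  paste0(triple$tier, " (", triple$pathogeny, ", ", triple$clinical_relevance, ")")
}

#' @export
print.classification_triple <- function(x, ...) {
  cat(x$tier, " (", x$pathogeny, ", ", x$clinical_relevance, ")\n", sep = "")
  invisible(x)
}

#' Parse the report dialect of HGVS variant notation
#'
#' The report dialect joins the cDNA and protein descriptions with an
#' underscore and may pad the substitution sign with spaces, e.g.
#' \code{"c.1799T > A_p.V600E"}. Internal spaces around \code{">"} are
#' stripped; the protein part is optional.
#'
#' @param text Raw notation string.
#' @return List with \code{cdna_change} (normalized, "c."/"g." prefixed) and
#'   \code{protein_change} (normalized "p." string or NULL).
#' @export
parse_variant_notation <- function(text) {
  parts <- strsplit(trimws(text), "_", fixed = TRUE)[[1]]
  norm <- function(s) gsub("\\s*>\\s*", ">", trimws(s))
  cdna <- norm(parts[1])
  if (!grepl("^[cg]\\.", cdna)) {
    stop("cannot parse variant notation '", text,
         "': expected a \"c.\" or \"g.\" prefixed change")
  }
  protein <- NULL
  if (length(parts) >= 2) {
    protein <- norm(parts[2])
    if (!grepl("^p\\.", protein)) {
      stop("cannot parse variant notation '", text,
           "': protein part must begin with \"p.\"")
    }
  }
  list(cdna_change = cdna, protein_change = protein)
}

#' Construct one reported variant
#'
#' \code{cdna_change}/\code{protein_change} are derived from
#' \code{hgvs_notation} via [parse_variant_notation()] when not supplied; the
#' raw notation string is preserved verbatim for display.
#'
#' @param gene_hgnc_id HGNC id, "HGNC:<digits>".
#' @param gene_symbol Gene symbol (e.g. "BRAF").
#' @param hgvs_notation Raw notation in the report dialect.
#' @param variant_effect Free-text effect (e.g. "Substitution (missense)").
#' @param variant_db_id Variant database id (e.g. COSMIC "COSM476").
#' @param classification A [classification_triple()] (or its printed form).
#' @param result_status,assay_code,observed_date,test_method,interpretation,comment
#'   Per-variant reporting metadata (required report elements).
#' @return Object of class \code{variant_record}.
#' @export
variant_record <- function(gene_hgnc_id = NULL, gene_symbol = NULL,
                           hgvs_notation = NULL, variant_effect = NULL,
                           variant_db_id = NULL, classification = NULL,
                           result_status = NULL, assay_code = NULL,
                           observed_date = NULL, test_method = NULL,
                           interpretation = NULL, comment = NULL) {
  parsed <- if (!is.null(hgvs_notation)) {
    tryCatch(parse_variant_notation(hgvs_notation),
             error = function(e) list(cdna_change = NULL, protein_change = NULL))
  } else list(cdna_change = NULL, protein_change = NULL)
  if (is.character(classification)) {
    classification <- parse_classification(classification)
  }
  structure(list(gene_hgnc_id = gene_hgnc_id, gene_symbol = gene_symbol,
                 hgvs_notation = hgvs_notation,
                 cdna_change = parsed$cdna_change,
                 protein_change = parsed$protein_change,
                 variant_effect = variant_effect,
                 variant_db_id = variant_db_id,
                 classification = classification,
                 result_status = result_status, assay_code = assay_code,
                 observed_date = observed_date, test_method = test_method,
                 interpretation = interpretation, comment = comment),
            class = "variant_record")
}

#' Construct a structured sequencing report
#'
#' @param subject Named list: identifier, name, birth_date, sex_code,
#'   ethnicity_code.
#' @param order Named list: order_id, order_date, ordering_clinician,
#'   legally_authorized_person, performing_laboratory.
#' @param report Named list: report_id, status, test_code, issued_date,
#'   interpretation_summary, assessed_condition.
#' @param specimen Named list: biomaterial_type, specimen_id, collection_date.
#' @param variants List of [variant_record()]s. \code{NULL} means the section
#'   is absent (non-conformant); an empty list is an explicit
#'   no-reportable-variants statement.
#' @param treatments List of recommended-treatment descriptors (strings).
#' @param research Optional named list keyed by optional element ids
#'   (\code{"research.*"}).
#' @return Object of class \code{sequencing_report}.
#' @export
sequencing_report <- function(subject = NULL, order = NULL, report = NULL,
                              specimen = NULL, variants = NULL,
                              treatments = NULL, research = NULL) {
  if (!is.null(research)) {
    reg <- load_element_registry()
    ids <- reg$element_id[reg$field_class == "optional"]
    bad <- setdiff(names(research), ids)
    if (length(bad) > 0) {
      stop("research keys not in the element registry: ", paste(bad, collapse = ", "))
    }
    research <- research[ids[ids %in% names(research)]]  # canonical order
    research <- research[!vapply(research, is.null, logical(1))]
    research <- lapply(research, .normalize_value)  # JSON-stable numerics
    if (length(research) == 0) research <- NULL
  }
  if (!is.null(treatments)) treatments <- as.list(treatments)
  structure(list(subject = subject, order = order, report = report,
                 specimen = specimen, variants = variants,
                 treatments = treatments, research = research),
            class = "sequencing_report")
}

#' @export
print.sequencing_report <- function(x, ...) {
  cat("<sequencing_report>\n")
  cat("  subject:   ", x$subject$name %||% "<absent>",
      " (", x$subject$identifier %||% "?", ")\n", sep = "")
  nv <- if (is.null(x$variants)) "<absent>" else length(x$variants)
  cat("  variants:  ", nv, "\n", sep = "")
  cat("  treatments:", length(x$treatments %||% list()), "\n")
  cat("  research:  ", length(x$research %||% list()), " optional fields\n", sep = "")
  invisible(x)
}

## ---- element accessors (registry id -> report value) ----

# Per-variant required elements live on each variant record.
.VARIANT_FIELD_MAP <- c(
  "genetic_variation.gene_hgnc_id" = "gene_hgnc_id",
  "genetic_variation.gene_symbol" = "gene_symbol",
  "genetic_variation.variant_notation" = "hgvs_notation",
  "genetic_variation.variant_effect" = "variant_effect",
  "genetic_variation.variant_db_id" = "variant_db_id",
  "genetic_variation.classification" = "classification",
  "genetic_variation.result_status" = "result_status",
  "genetic_variation.assay_code" = "assay_code",
  "genetic_variation.observed_date" = "observed_date",
  "genetic_variation.test_method" = "test_method",
  "genetic_variation.interpretation" = "interpretation",
  "genetic_variation.comment" = "comment")

.REPORT_FIELD_MAP <- list(
  "order.order_id" = c("order", "order_id"),
  "order.order_date" = c("order", "order_date"),
  "order.ordering_clinician" = c("order", "ordering_clinician"),
  "order.legally_authorized_person" = c("order", "legally_authorized_person"),
  "order.performing_laboratory" = c("order", "performing_laboratory"),
  "subject.identifier" = c("subject", "identifier"),
  "subject.name" = c("subject", "name"),
  "subject.birth_date" = c("subject", "birth_date"),
  "subject.sex" = c("subject", "sex_code"),
  "subject.ethnicity" = c("subject", "ethnicity_code"),
  "report.report_id" = c("report", "report_id"),
  "report.status" = c("report", "status"),
  "report.test_code" = c("report", "test_code"),
  "report.issued_date" = c("report", "issued_date"),
  "report.interpretation_summary" = c("report", "interpretation_summary"),
  "report.assessed_condition" = c("report", "assessed_condition"),
  "specimen.biomaterial_type" = c("specimen", "biomaterial_type"),
  "specimen.specimen_id" = c("specimen", "specimen_id"),
  "specimen.collection_date" = c("specimen", "collection_date"))

#' Value of a registry element within a report
#'
#' For report-level elements returns the scalar (or composite) value; for
#' per-variant elements returns a list with one value per variant; for
#' \code{treatment.recommended_treatment} the treatments list.
#'
#' @param report A \code{sequencing_report}.
#' @param element_id Registry element key.
#' @return The value, or NULL when unpopulated.
#' @export
report_element_value <- function(report, element_id) {
  if (element_id %in% names(.REPORT_FIELD_MAP)) {
    p <- .REPORT_FIELD_MAP[[element_id]]
    return(report[[p[1]]][[p[2]]])
  }
  if (element_id %in% names(.VARIANT_FIELD_MAP)) {
    if (is.null(report$variants)) return(NULL)
    f <- .VARIANT_FIELD_MAP[[element_id]]
    return(lapply(report$variants, `[[`, f))
  }
  if (element_id == "treatment.recommended_treatment") return(report$treatments)
  if (startsWith(element_id, "research.")) return(report$research[[element_id]])
  element_lookup(element_id)  # errors informatively on unknown ids
  NULL
}

## ---- report document (JSON / YAML) ----

.variant_to_doc <- function(v) {
  doc <- list()
  for (id in names(.VARIANT_FIELD_MAP)) {
    val <- v[[.VARIANT_FIELD_MAP[[id]]]]
    if (inherits(val, "classification_triple")) val <- format_classification(val)
    if (!is.null(val)) doc[[id]] <- val
  }
  doc
}

#' Write / read a report document
#'
#' The document format is JSON keyed by element id (YAML is accepted on
#' input): report-level scalars under their dot-path ids, variants as an array
#' of element-id-keyed objects, the classification in its printed form.
#'
#' @param report A \code{sequencing_report}.
#' @param path File path (.json, .yaml/.yml for read).
#' @return `write_report` the path invisibly; `read_report` the report.
#' @export
write_report <- function(report, path) {
  doc <- list()
  for (id in names(.REPORT_FIELD_MAP)) {
    val <- report_element_value(report, id)
    if (!is.null(val)) doc[[id]] <- val
  }
  if (!is.null(report$variants)) {
    doc[["variants"]] <- lapply(report$variants, .variant_to_doc)
  }
  if (!is.null(report$treatments)) {
    doc[["treatment.recommended_treatment"]] <- report$treatments
  }
  if (!is.null(report$research)) doc[["research"]] <- report$research
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  pick <- function(section) {
    keys <- names(.REPORT_FIELD_MAP)[vapply(.REPORT_FIELD_MAP, function(p) p[1] == section, logical(1))]
    out <- list()
    for (id in keys) {
      if (!is.null(doc[[id]])) out[[.REPORT_FIELD_MAP[[id]][2]]] <- doc[[id]]
    }
    if (length(out) == 0) NULL else out
  }
  variants <- NULL
  if (!is.null(doc$variants)) {
    variants <- lapply(doc$variants, function(vd) {
      args <- list()
      for (id in names(.VARIANT_FIELD_MAP)) {
        args[[.VARIANT_FIELD_MAP[[id]]]] <- vd[[id]]
      }
      names(args)[names(args) == "hgvs_notation"] <- "hgvs_notation"
      do.call(variant_record, args)
    })
  }
  research <- doc$research
  if (!is.null(research)) {
    research <- lapply(research, function(v) if (is.list(v)) lapply(v, .normalize_value) else .normalize_value(v))
  }
  sequencing_report(subject = pick("subject"), order = pick("order"),
                    report = pick("report"), specimen = pick("specimen"),
                    variants = variants,
                    treatments = doc[["treatment.recommended_treatment"]],
                    research = research)
}
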