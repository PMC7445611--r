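# Report <-> bundle conversion. build_bundle() places every populated element
# at the slots the mapping table defines (one Observation per variant,
# demographics on a Patient dereferenced from DiagnosticReport.subject,
# free-standing Medication entries referenced from a DiagnosticReport
# extension, research fields on MolecularSequence/Device/Condition and a
# biomarker-summary Observation). extract_report() inverts it on the image,
# reading values back through the mapping table's structural paths.

.compact <- function(x) {
  x <- x[!vapply(x, is.null, logical(1))]
  if (length(x) == 0) NULL else x
}

.format_issues <- function(issues) {
  paste(sprintf("[%s] %s %s: %s", issues$severity, issues$code,
                issues$element_id, issues$message), collapse = "\n  ")
}

.PATIENT_REF <- "Patient/patient-1"

.build_variant_obs <- function(v, i, specimen_id) {
  obs <- make_resource("Observation", .compact(list(
    status = v$result_status,
    code = v$assay_code,
    effectiveDateTime = v$observed_date,
    method = v$test_method,
    interpretation = v$interpretation,
    comment = v$comment,
    subject = fhir_reference(.PATIENT_REF),
    specimen = if (!is.null(specimen_id)) list(identifier = specimen_id)
  )) %||% list(), id = paste0("observation-variant-", i))
  addx <- function(res, name, value) {
    if (is.null(value)) res else add_extension(res, .ext_url(name), value)
  }
  obs <- addx(obs, "observation-geneticsGeneId", v$gene_hgnc_id)
  obs <- addx(obs, "observation-geneticsGene", v$gene_symbol)
  obs <- addx(obs, "observation-geneticsDNASequenceVariantName", v$hgvs_notation)
  obs <- addx(obs, "observation-geneticsDNASequenceVariantType", v$variant_effect)
  obs <- addx(obs, "observation-geneticsDNAVariantId", v$variant_db_id)
  if (!is.null(v$classification)) {
    cl <- v$classification
    obs <- add_extension(obs, .ext_url("observation-classificationVariants"),
                         list(Tier = cl$tier, Pathogeny = cl$pathogeny,
                              ClinicalRelavance = cl$clinical_relevance))
  }
  obs
}

# component key (snake_case) -> sub-extension / component name for an element,
# taken from the mapping table so builder and table cannot drift apart
.component_names <- function(element_id) {
  rows <- element_slots(element_id)
  rows <- rows[!is.na(rows$component), , drop = FALSE]
  nm <- sub("^.*[.(]([A-Za-z0-9]+)\\)?$", "\\1", rows$structural_path)
  stats::setNames(nm, rows$component)
}

.build_research <- function(research) {
  g <- function(key) research[[paste0("research.", key)]]
  out <- list()

  molseq_vals <- .compact(list(
    type = g("sequence_type"),
    coordinateSystem = g("coordinate_system"),
    referenceSeq = .compact(list(
      chromosome = g("chromosome"),
      genomeBuild = g("reference_assembly"),
      referenceSeqId = g("reference_seq_id"),
      strand = g("strand"),
      windowStart = g("sequence_window")$start,
      windowEnd = g("sequence_window")$end)),
    variant = .compact(list(
      start = g("variant_position")$start,
      end = g("variant_position")$end,
      observedAllele = g("observed_allele"),
      referenceAllele = g("reference_allele"))),
    readCoverage = g("read_coverage"),
    quality = .compact(list(score = g("quality_score"))),
    repository = .compact(list(url = g("repository_pointer")$url,
                               name = g("repository_pointer")$name))
  ))
  seqplat <- g("sequencing_platform")
  anaplat <- g("analysis_platform")
  has_molseq_ext <- !is.null(seqplat) || !is.null(anaplat) ||
    !is.null(g("base_calling")) || !is.null(g("qc_metrics"))
  if (!is.null(molseq_vals) || has_molseq_ext) {
    ms <- make_resource("MolecularSequence",
                        c(list(patient = fhir_reference(.PATIENT_REF)),
                          molseq_vals %||% list()),
                        id = "molecularsequence-1")
    if (!is.null(seqplat)) {
      ms <- add_extension(ms, .ext_url("molecularsequence-sequencingPlatform"), seqplat)
    }
    if (!is.null(anaplat)) {
      ms <- add_extension(ms, .ext_url("molecularsequence-analysisPlatform"), anaplat)
    }
    if (!is.null(g("base_calling"))) {
      ms <- add_extension(ms, .ext_url("molecularsequence-baseCalling"), g("base_calling"))
    }
    if (!is.null(g("qc_metrics"))) {
      qc <- g("qc_metrics")
      nm <- .component_names("research.qc_metrics")
      val <- stats::setNames(qc, nm[names(qc)])
      ms <- add_extension(ms, .ext_url("molecularsequence-qcMetrics"), val)
    }
    out <- c(out, list(ms))
  }

  dev_body <- .compact(list(manufacturer = seqplat$manufacturer,
                            model = seqplat$model,
                            version = anaplat$version))
  has_dev_ext <- !is.null(anaplat$name) || !is.null(g("base_calling")) ||
    !is.null(g("flowcell_id"))
  if (!is.null(dev_body) || has_dev_ext) {
    dev <- make_resource("Device", dev_body %||% list(), id = "device-1")
    if (!is.null(anaplat$name)) {
      dev <- add_extension(dev, .ext_url("device-analysisPipeline"), anaplat$name)
    }
    if (!is.null(g("base_calling"))) {
      dev <- add_extension(dev, .ext_url("device-baseCallingAlgorithm"), g("base_calling"))
    }
    if (!is.null(g("flowcell_id"))) {
      dev <- add_extension(dev, .ext_url("device-flowcellId"), g("flowcell_id"))
    }
    out <- c(out, list(dev))
  }

  if (!is.null(g("condition_code"))) {
    out <- c(out, list(make_resource("Condition",
                                     list(code = g("condition_code"),
                                          subject = fhir_reference(.PATIENT_REF)),
                                     id = "condition-1")))
  }

  biomarker_ids <- c("research.tumor_mutational_burden",
                     "research.microsatellite_status", "research.tumor_purity",
                     "research.hrd_score", "research.mutational_signature",
                     "research.circulating_dna_fraction")
  present <- biomarker_ids[biomarker_ids %in% names(research)]
  if (length(present) > 0) {
    comps <- lapply(present, function(id) {
      cname <- sub("^Observation\\.component\\(([^)]+)\\)$", "\\1",
                   map_element(id)$structural_path)
      list(code = list(text = cname), value = research[[id]])
    })
    ro <- make_resource("Observation",
                        list(subject = fhir_reference(.PATIENT_REF),
                             component = comps),
                        id = "observation-research-1")
    for (id in present) {
      row <- element_slots(id)
      row <- row[row$mapping_kind == "extension", , drop = FALSE]
      ro <- add_extension(ro, row$extension_url[1], research[[id]])
    }
    out <- c(out, list(ro))
  }
  out
}

#' Build a FHIR bundle from a sequencing report
#'
#' Refuses reports with error-severity validation issues. The resulting bundle
#' contains one DiagnosticReport, one Patient, one ProcedureRequest, one
#' Observation per variant (genetics extensions per the mapping table),
#' free-standing Medication entries per recommended treatment, and — when
#' research fields are present — MolecularSequence, Device, Condition and a
#' biomarker Observation. DiagnosticReport.result references each variant
#' Observation.
#'
#' @param report A conformant \code{sequencing_report}.
#' @param bundle_type "collection" (default) or "transaction".
#' @param id_prefix Optional prefix applied to every logical id (and internal
#'   reference), so several report bundles can share one repository.
#' @return A \code{fhir_bundle}.
#' @export
build_bundle <- function(report, bundle_type = "collection", id_prefix = "") {
  issues <- validate_report(report)
  if (any(issues$severity == "error")) {
    stop("report fails validation:\n  ",
         .format_issues(issues[issues$severity == "error", , drop = FALSE]))
  }
  s <- report$subject; o <- report$order; rp <- report$report; sp <- report$specimen

  patient <- make_resource("Patient", .compact(list(
    identifier = s$identifier, name = s$name, birthDate = s$birth_date
  )) %||% list(), id = "patient-1")
  if (!is.null(s$sex_code)) {
    patient <- add_extension(patient, .ext_url("patient-sexIso22220"), s$sex_code)
  }
  if (!is.null(s$ethnicity_code)) {
    patient <- add_extension(patient, .ext_url("patient-ethnicity"), s$ethnicity_code)
  }

  pr <- make_resource("ProcedureRequest", .compact(list(
    identifier = o$order_id, authoredOn = o$order_date,
    requester = o$ordering_clinician, subject = fhir_reference(.PATIENT_REF)
  )) %||% list(), id = "procedurerequest-1")

  variants <- report$variants %||% list()
  var_obs <- list()
  if (length(variants) > 0) {
    var_obs <- lapply(seq_along(variants), function(i) {
      .build_variant_obs(variants[[i]], i, sp$specimen_id)
    })
  }

  treatments <- report$treatments %||% list()
  meds <- lapply(seq_along(treatments), function(k) {
    make_resource("Medication", list(code = treatments[[k]]),
                  id = paste0("medication-", k))
  })

  dr <- make_resource("DiagnosticReport", .compact(list(
    identifier = rp$report_id, status = rp$status, code = rp$test_code,
    issued = rp$issued_date, conclusion = rp$interpretation_summary,
    performer = o$performing_laboratory,
    subject = fhir_reference(.PATIENT_REF),
    specimen = .compact(list(display = sp$biomaterial_type,
                             identifier = sp$specimen_id)),
    result = if (length(var_obs) > 0) {
      lapply(var_obs, function(ob) fhir_reference(paste0("Observation/", ob$id)))
    },
    codedDiagnosis = report$research[["research.coded_diagnosis"]],
    category = report$research[["research.report_category"]]
  )) %||% list(), id = "diagnosticreport-1")
  addx <- function(res, name, value) {
    if (is.null(value)) res else add_extension(res, .ext_url(name), value)
  }
  dr <- addx(dr, "diagnosticreport-legallyAuthorizedRepresentative",
             o$legally_authorized_person)
  dr <- addx(dr, "diagnosticreport-assessedCondition", rp$assessed_condition)
  dr <- addx(dr, "diagnosticreport-specimenCollectionDate", sp$collection_date)
  for (med in meds) {
    dr <- add_extension(dr, .ext_url("diagnosticreport-recommendedTreatment"),
                        fhir_reference(paste0("Medication/", med$id)))
  }
  dr <- addx(dr, "diagnosticreport-researchStudy",
             report$research[["research.study_id"]])
  dr <- addx(dr, "diagnosticreport-researchConsent",
             report$research[["research.consent_status"]])

  research_entries <- if (!is.null(report$research)) {
    .build_research(report$research)
  } else list()

  bundle <- fhir_bundle(c(list(patient, pr, dr), var_obs, meds, research_entries),
                        bundle_type = bundle_type)
  if (nzchar(id_prefix)) bundle <- .prefix_bundle_ids(bundle, id_prefix)
  bundle
}

# prepend a prefix to every entry id and rewrite internal references
.prefix_bundle_ids <- function(bundle, prefix) {
  old_keys <- vapply(bundle$entries, function(r) paste0(r$resource_type, "/", r$id),
                     character(1))
  rewrite <- function(v) {
    if (inherits(v, "fhir_reference")) {
      if (v$reference %in% old_keys) {
        parts <- strsplit(v$reference, "/", fixed = TRUE)[[1]]
        return(fhir_reference(paste0(parts[1], "/", prefix, parts[2])))
      }
      return(v)
    }
    if (is.list(v)) return(lapply(v, rewrite))
    v
  }
  bundle$entries <- lapply(bundle$entries, function(r) {
    r$id <- paste0(prefix, r$id)
    r$body <- rewrite(r$body)
    r$extension <- lapply(r$extension, function(e) {
      e$value <- rewrite(e$value)
      e
    })
    r
  })
  bundle
}

## ---- extraction ----

.walk_resource <- function(bundle, resource, path) {
  segs <- .parse_path(path)
  .walk_segments(bundle, resource, segs[-1])
}

.first_or_null <- function(v) if (length(v) > 0) v[[1]] else NULL

# Generic mapping-driven read of a report-level element from the bundle.
.element_from_bundle <- function(bundle, element_id) {
  rows <- element_slots(element_id)
  prim <- rows[rows$primary, , drop = FALSE]
  if (is.na(prim$component) || identical(prim$component, "reference")) {
    return(.first_or_null(walk_bundle_path(bundle, prim$structural_path)))
  }
  # composite element: assemble named components from the primary resource's rows
  part_rows <- rows[!is.na(rows$component) &
                      rows$resource_type == prim$resource_type, , drop = FALSE]
  vals <- lapply(seq_len(nrow(part_rows)), function(i) {
    .first_or_null(walk_bundle_path(bundle, part_rows$structural_path[i]))
  })
  names(vals) <- part_rows$component
  .compact(vals)
}

.extract_variant <- function(bundle, obs) {
  w1 <- function(path) .first_or_null(.walk_resource(bundle, obs, path))
  cl_rows <- element_slots("genetic_variation.classification")
  cl <- .compact(stats::setNames(
    lapply(cl_rows$structural_path, function(p) w1(p)), cl_rows$component))
  classification <- if (!is.null(cl)) {
    classification_triple(cl$tier %||% NA_character_,
                          cl$pathogeny %||% NA_character_,
                          cl$clinical_relevance %||% NA_character_,
                          validate = FALSE)
  }
  path_of <- function(id) map_element(id)$structural_path
  variant_record(
    gene_hgnc_id = w1(path_of("genetic_variation.gene_hgnc_id")),
    gene_symbol = w1(path_of("genetic_variation.gene_symbol")),
    hgvs_notation = w1(path_of("genetic_variation.variant_notation")),
    variant_effect = w1(path_of("genetic_variation.variant_effect")),
    variant_db_id = w1(path_of("genetic_variation.variant_db_id")),
    classification = classification,
    result_status = w1(path_of("genetic_variation.result_status")),
    assay_code = w1(path_of("genetic_variation.assay_code")),
    observed_date = w1(path_of("genetic_variation.observed_date")),
    test_method = w1(path_of("genetic_variation.test_method")),
    interpretation = w1(path_of("genetic_variation.interpretation")),
    comment = w1(path_of("genetic_variation.comment")))
}

#' Extract a sequencing report from a bundle
#'
#' Inverse of [build_bundle()] on its image: values are read back through the
#' mapping table's structural paths. Extensions whose URL is not registered in
#' the mapping are collected into the \code{"unmapped"} attribute of the
#' result, never dropped silently.
#'
#' @param bundle A \code{fhir_bundle} shaped like [build_bundle()] output.
#' @return A \code{sequencing_report}; attribute \code{"unmapped"} lists
#'   (resource, url) pairs for unrecognized extensions.
#' @export
extract_report <- function(bundle) {
  stopifnot(inherits(bundle, "fhir_bundle"))
  dr <- NULL
  for (r in bundle$entries) if (r$resource_type == "DiagnosticReport") { dr <- r; break }
  if (is.null(dr)) stop("cannot extract report: bundle has no DiagnosticReport")

  e <- function(id) .element_from_bundle(bundle, id)
  subject <- .compact(list(
    identifier = e("subject.identifier"), name = e("subject.name"),
    birth_date = e("subject.birth_date"), sex_code = e("subject.sex"),
    ethnicity_code = e("subject.ethnicity")))
  order <- .compact(list(
    order_id = e("order.order_id"), order_date = e("order.order_date"),
    ordering_clinician = e("order.ordering_clinician"),
    legally_authorized_person = e("order.legally_authorized_person"),
    performing_laboratory = e("order.performing_laboratory")))
  report_meta <- .compact(list(
    report_id = e("report.report_id"), status = e("report.status"),
    test_code = e("report.test_code"), issued_date = e("report.issued_date"),
    interpretation_summary = e("report.interpretation_summary"),
    assessed_condition = e("report.assessed_condition")))
  specimen <- .compact(list(
    biomaterial_type = e("specimen.biomaterial_type"),
    specimen_id = e("specimen.specimen_id"),
    collection_date = e("specimen.collection_date")))

  refs <- dr$body$result %||% list()
  variants <- lapply(refs, function(ref) {
    obs <- resolve_reference(bundle, ref$reference)
    if (is.null(obs)) stop("DiagnosticReport.result reference '", ref$reference,
                           "' does not resolve within the bundle")
    .extract_variant(bundle, obs)
  })

  treatments <- walk_bundle_path(bundle, "Medication.code")
  if (length(treatments) == 0) treatments <- NULL

  reg <- load_element_registry()
  opt_ids <- reg$element_id[reg$field_class == "optional"]
  research <- .compact(stats::setNames(lapply(opt_ids, e), opt_ids))

  out <- sequencing_report(subject = subject, order = order,
                           report = report_meta, specimen = specimen,
                           variants = variants, treatments = treatments,
                           research = research)
  attr(out, "unmapped") <- .unmapped_extensions(bundle)
  out
}

# extensions whose (fragment-stripped) URL is not a registered definition
.unmapped_extensions <- function(bundle) {
  known <- unique(sub("#.*$", "", extension_definitions()$url))
  out <- list()
  for (r in bundle$entries) {
    for (ext in r$extension) {
      if (!sub("#.*$", "", ext$url) %in% known) {
        out <- c(out, list(list(resource = paste0(r$resource_type, "/", r$id),
                                url = ext$url)))
      }
    }
  }
  out
}
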