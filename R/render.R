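# Clinician summary renderer: extracts the report from a bundle and renders
# the three sections of the clinician-facing view — variant results, the
# interpretation summary, and information about the test. Output is
# deterministic plain text plus a standalone HTML document.

.render_variant_lines <- function(variants) {
  if (length(variants) == 0) {
    return("No reportable variants.")
  }
  vapply(variants, function(v) {
    cls <- tryCatch(format_classification(v$classification),
                    error = function(e) "<unclassified>")
    sprintf("%s (%s)  %s  [%s]  %s  %s",
            v$gene_symbol %||% "?", v$gene_hgnc_id %||% "?",
            v$hgvs_notation %||% "?", v$variant_effect %||% "?",
            cls, v$variant_db_id %||% "")
  }, character(1))
}

#' Render the clinician summary of a bundle
#'
#' @param bundle A \code{fhir_bundle} built by (or shaped like)
#'   [build_bundle()] output.
#' @return List with components \code{text} and \code{html}; both contain the
#'   three labeled sections (variant results, interpretation summary, test
#'   information) and are byte-stable for a given bundle.
#' @export
render_summary <- function(bundle) {
  report <- tryCatch(extract_report(bundle), error = function(e) {
    stop("cannot render summary: ", conditionMessage(e))
  })
  s <- report$subject; o <- report$order; rp <- report$report; sp <- report$specimen
  variant_lines <- .render_variant_lines(report$variants %||% list())
  treatments <- vapply(report$treatments %||% list(), as.character, character(1))
  test_info <- c(
    sprintf("Subject: %s (%s), born %s", s$name %||% "?", s$identifier %||% "?",
            s$birth_date %||% "?"),
    sprintf("Test: %s  Report: %s  Status: %s  Issued: %s",
            rp$test_code %||% "?", rp$report_id %||% "?", rp$status %||% "?",
            rp$issued_date %||% "?"),
    sprintf("Specimen: %s (%s), collected %s", sp$biomaterial_type %||% "?",
            sp$specimen_id %||% "?", sp$collection_date %||% "?"),
    sprintf("Performing laboratory: %s", o$performing_laboratory %||% "?"),
    if (length(treatments) > 0) {
      sprintf("Recommended treatment(s): %s", paste(treatments, collapse = ", "))
    })
  text <- paste(c(
    "== VARIANT RESULTS ==", variant_lines, "",
    "== INTERPRETATION SUMMARY ==", rp$interpretation_summary %||% "", "",
    "== TEST INFORMATION ==", test_info), collapse = "\n")

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  li <- function(xs) paste0("<li>", esc(xs), "</li>", collapse = "\n")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>Clinical sequencing report</title></head><body>\n",
    "<h1>Clinical sequencing report</h1>\n",
    "<h2>Variant results</h2>\n<ul>\n", li(variant_lines), "\n</ul>\n",
    "<h2>Interpretation summary</h2>\n<p>",
    esc(rp$interpretation_summary %||% ""), "</p>\n",
    "<h2>Test information</h2>\n<ul>\n", li(test_info), "\n</ul>\n",
    "</body></html>\n")
  list(text = text, html = html)
}
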