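# Structural-path walker over bundles. Structural paths back the display
# paths of the mapping table and use a small dot-separated grammar:
#
#   Type                      root resource type (all entries of that type)
#   field                     plain body field (or sub-field of the current node)
#   field(patient)            dereference: follow field$reference to the target
#   extension(name)           extension whose URL basename is `name`
#   Sub                       sub-extension `Sub` of the preceding extension node
#   component(code)           Observation component whose code$text is `code`
#
# The walker is independent of the bundle builder: it evaluates paths purely
# against the generic resource model, which makes it usable as a
# field-placement oracle.

.parse_path <- function(path) {
  strsplit(path, ".", fixed = TRUE)[[1]]
}

.ext_basename <- function(url) sub("^.*/", "", sub("#.*$", "", url))

# Walk one resource with the remaining segments; returns list of values.
.walk_segments <- function(bundle, node, segs, in_extension = FALSE) {
  if (length(segs) == 0) {
    return(if (is.null(node)) list() else list(node))
  }
  seg <- segs[[1]]
  rest <- segs[-1]
  deref <- regmatches(seg, regexec("^([A-Za-z]+)\\(([A-Za-z0-9-]+)\\)$", seg))[[1]]
  if (length(deref) == 3 && deref[2] == "extension") {
    # extension(name): collect matching extensions of the current resource
    stopifnot(inherits(node, "fhir_resource"))
    name <- deref[3]
    hits <- Filter(function(e) .ext_basename(e$url) == name, node$extension)
    out <- list()
    for (e in hits) out <- c(out, .walk_segments(bundle, e$value, rest, TRUE))
    return(out)
  }
  if (length(deref) == 3 && deref[2] == "component") {
    stopifnot(inherits(node, "fhir_resource"))
    comps <- node$body$component %||% list()
    hits <- Filter(function(cp) identical(cp$code$text, deref[3]), comps)
    out <- list()
    for (cp in hits) out <- c(out, .walk_segments(bundle, cp$value, rest, FALSE))
    return(out)
  }
  if (length(deref) == 3) {
    # field(type) dereference through an internal reference
    stopifnot(inherits(node, "fhir_resource"))
    ref <- node$body[[deref[2]]]
    refstr <- if (inherits(ref, "fhir_reference")) ref$reference else ref$reference
    if (is.null(refstr)) return(list())
    target <- resolve_reference(bundle, refstr)
    if (is.null(target)) return(list())
    return(.walk_segments(bundle, target, rest, FALSE))
  }
  # plain segment
  nxt <- if (inherits(node, "fhir_resource")) {
    if (in_extension) stop("internal walker state error")
    node$body[[seg]]
  } else if (is.list(node)) {
    node[[seg]]
  } else {
    NULL
  }
  .walk_segments(bundle, nxt, rest, in_extension && is.list(nxt))
}

#' Walk a structural path over a bundle
#'
#' Evaluates a mapping-table \code{structural_path} against a bundle and
#' returns every value found (one per matching resource/extension occurrence).
#' Used both by report extraction and, independently, as the field-placement
#' oracle in the test suite.
#'
#' @param bundle A \code{fhir_bundle}.
#' @param path Structural path string, e.g.
#'   \code{"DiagnosticReport.subject(patient).birthDate"}.
#' @return List of values (empty when nothing is populated at the path).
#' @export
walk_bundle_path <- function(bundle, path) {
  stopifnot(inherits(bundle, "fhir_bundle"))
  segs <- .parse_path(path)
  root_type <- segs[[1]]
  out <- list()
  for (r in bundle$entries) {
    if (r$resource_type == root_type) {
      out <- c(out, .walk_segments(bundle, r, segs[-1]))
    }
  }
  out
}
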