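# Minimal generic FHIR (STU3-dialect) resource model: the eight mapped
# resource types plus Bundle, with URL-identified extensions (flat or complex),
# canonical JSON serialization and internal-reference validation. The element
# dialect is deliberately loose — bodies are ordered maps of scalars, nested
# maps and lists — because profile-level typing is carried by the mapping
# table, not by the resource container.

FHIR_RESOURCE_TYPES <- c("ProcedureRequest", "DiagnosticReport", "Observation",
                         "Medication", "Patient", "Condition",
                         "MolecularSequence", "Device")

# Normalize a body so that JSON round-trips are identity: integers widen to
# double, atomic vectors of length > 1 become lists (JSON arrays).
.normalize_value <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "fhir_reference")) return(x)
  if (is.list(x)) return(lapply(x, .normalize_value))
  if (is.integer(x)) x <- as.numeric(x)
  if (is.atomic(x) && length(x) > 1) return(lapply(as.list(x), .normalize_value))
  x
}

#' Construct a FHIR resource
#'
#' @param resource_type One of the supported resource types (see
#'   \code{FHIR_RESOURCE_TYPES}).
#' @param body Named list of element values (scalars, nested lists).
#' @param id Logical id; a fresh one is minted when omitted.
#' @return An object of class \code{fhir_resource} with \code{version_id = 1}.
#' @examples
#' make_resource("Patient", list(birthDate = "1947-04-29"))
#' @export
make_resource <- function(resource_type, body = list(), id = NULL) {
  if (!resource_type %in% FHIR_RESOURCE_TYPES) {
    stop("unsupported resource type '", resource_type, "'; supported: ",
         paste(FHIR_RESOURCE_TYPES, collapse = ", "))
  }
  if (is.null(id)) {
    n <- (.seqreport_env$id_counter %||% 0L) + 1L
    .seqreport_env$id_counter <- n
    id <- paste0(tolower(resource_type), "-", n)
  }
  structure(list(resource_type = resource_type, id = id, version_id = 1,
                 body = .normalize_value(body), extension = list()),
            class = "fhir_resource")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A FHIR reference value
#' @param reference Target in "ResourceType/id" form.
#' @export
fhir_reference <- function(reference) {
  structure(list(reference = reference), class = "fhir_reference")
}

#' Append an extension to a resource
#'
#' Repeated URLs are allowed and preserved in order. A named-list value is
#' serialized as a complex extension (sub-extensions keyed by name); a
#' [fhir_reference()] value becomes \code{valueReference}.
#'
#' @param resource A \code{fhir_resource}.
#' @param url Absolute extension URL.
#' @param value Typed value (string, number, logical, named list, reference).
#' @return The resource with the extension appended.
#' @export
add_extension <- function(resource, url, value) {
  stopifnot(inherits(resource, "fhir_resource"))
  if (!grepl("^https?://", url)) {
    stop("extension url must be absolute, got '", url, "'")
  }
  resource$extension <- c(resource$extension,
                          list(list(url = url, value = .normalize_value(value))))
  resource
}

#' Extension values on a resource for one URL
#' @param resource A \code{fhir_resource}.
#' @param url Absolute extension URL.
#' @return List of values (possibly empty; repeated extensions give several).
#' @export
get_extension_values <- function(resource, url) {
  vals <- lapply(resource$extension, function(e) if (e$url == url) e$value)
  vals[!vapply(vals, is.null, logical(1))]
}

#' Construct a bundle of resources
#' @param entries List of \code{fhir_resource} objects.
#' @param bundle_type "collection" (default) or "transaction".
#' @export
fhir_bundle <- function(entries = list(), bundle_type = c("collection", "transaction")) {
  bundle_type <- match.arg(bundle_type)
  stopifnot(all(vapply(entries, inherits, logical(1), "fhir_resource")))
  structure(list(bundle_type = bundle_type, entries = entries),
            class = "fhir_bundle")
}

## ---- JSON serialization ----

.serialize_ext_value <- function(value) {
  if (inherits(value, "fhir_reference")) {
    list(valueReference = list(reference = value$reference))
  } else if (is.list(value) && !is.null(names(value))) {
    list(extension = lapply(names(value), function(nm) {
      c(list(url = nm), .serialize_ext_value(value[[nm]]))
    }))
  } else if (is.character(value)) {
    list(valueString = value)
  } else if (is.numeric(value)) {
    list(valueDecimal = value)
  } else if (is.logical(value)) {
    list(valueBoolean = value)
  } else {
    stop("cannot serialize extension value of class ", paste(class(value), collapse = "/"))
  }
}

.serialize_body_value <- function(x) {
  if (inherits(x, "fhir_reference")) list(reference = x$reference)
  else if (is.list(x)) lapply(x, .serialize_body_value)
  else x
}

.resource_to_list <- function(resource) {
  out <- list(resourceType = resource$resource_type, id = resource$id,
              meta = list(versionId = as.character(resource$version_id)))
  if (length(resource$extension) > 0) {
    out$extension <- lapply(resource$extension, function(e) {
      c(list(url = e$url), .serialize_ext_value(e$value))
    })
  }
  c(out, .serialize_body_value(resource$body))
}

.bundle_to_list <- function(bundle) {
  list(resourceType = "Bundle", type = bundle$bundle_type,
       entry = lapply(bundle$entries, function(r) list(resource = .resource_to_list(r))))
}

#' Serialize a resource or bundle to canonical JSON
#'
#' Keys are emitted in fixed schema order (resourceType, id, meta, extension,
#' then body elements in insertion order); output is newline-terminated UTF-8.
#' \code{from_json(to_json(x))} is the identity.
#'
#' @param x A \code{fhir_resource} or \code{fhir_bundle}.
#' @param pretty Pretty-print (default TRUE).
#' @return A JSON string.
#' @export
to_json <- function(x, pretty = TRUE) {
  lst <- if (inherits(x, "fhir_bundle")) .bundle_to_list(x)
         else if (inherits(x, "fhir_resource")) .resource_to_list(x)
         else stop("to_json expects a fhir_resource or fhir_bundle")
  txt <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = pretty)
  paste0(as.character(txt), "\n")
}

.EXT_VALUE_KEYS <- c("valueString", "valueDecimal", "valueInteger",
                     "valueBoolean", "valueCode", "valueDate", "valueReference")

.deserialize_ext <- function(e) {
  if (!is.null(e$extension)) {
    subs <- lapply(e$extension, .deserialize_ext)
    value <- stats::setNames(lapply(subs, `[[`, "value"),
                             vapply(subs, `[[`, character(1), "url"))
  } else {
    key <- intersect(.EXT_VALUE_KEYS, names(e))
    if (length(key) == 0) stop("extension '", e$url, "' has no value[x] or sub-extensions")
    v <- e[[key[1]]]
    value <- if (key[1] == "valueReference") fhir_reference(v$reference)
             else if (key[1] == "valueInteger") as.numeric(v)
             else v
  }
  list(url = e$url, value = .normalize_value(value))
}

.deserialize_body_value <- function(x) {
  if (is.list(x)) {
    if (identical(names(x), "reference")) return(fhir_reference(x$reference))
    lapply(x, .deserialize_body_value)
  } else .normalize_value(x)
}

.list_to_resource <- function(lst) {
  rt <- lst$resourceType
  if (is.null(rt)) stop("JSON object has no resourceType member")
  if (!rt %in% FHIR_RESOURCE_TYPES) {
    stop("unsupported resource type '", rt, "'; supported: ",
         paste(FHIR_RESOURCE_TYPES, collapse = ", "))
  }
  version <- as.numeric(lst$meta$versionId %||% 1)
  ext <- lapply(lst$extension %||% list(), .deserialize_ext)
  body <- lst[setdiff(names(lst), c("resourceType", "id", "meta", "extension"))]
  res <- make_resource(rt, id = lst$id %||% "unidentified")
  res$version_id <- version
  res$extension <- ext
  res$body <- .deserialize_body_value(body)
  res
}

#' Parse FHIR JSON into a resource or bundle
#'
#' @param text JSON string (or path to a single-document JSON file).
#' @return A \code{fhir_resource} or \code{fhir_bundle}.
#' @export
from_json <- function(text) {
  if (length(text) == 1 && !grepl("\\{", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  lst <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON: ", conditionMessage(e)))
  if (is.null(lst$resourceType)) stop("JSON object has no resourceType member")
  if (identical(lst$resourceType, "Bundle")) {
    entries <- lapply(lst$entry %||% list(), function(en) .list_to_resource(en$resource))
    fhir_bundle(entries, bundle_type = lst$type %||% "collection")
  } else {
    .list_to_resource(lst)
  }
}

## ---- reference validation ----

.collect_references <- function(x) {
  refs <- character(0)
  walk <- function(v) {
    if (inherits(v, "fhir_reference")) {
      refs <<- c(refs, v$reference)
    } else if (is.list(v)) {
      if (!is.null(v[["reference"]]) && is.character(v[["reference"]])) {
        refs <<- c(refs, v[["reference"]])
      }
      for (el in v) walk(el)
    }
  }
  walk(x)
  refs
}

#' Find unresolved internal references in a bundle
#'
#' @param bundle A \code{fhir_bundle}.
#' @return Character vector of "ResourceType/id" references that do not
#'   resolve to a bundle entry (empty when the bundle is closed).
#' @export
validate_bundle_refs <- function(bundle) {
  stopifnot(inherits(bundle, "fhir_bundle"))
  present <- vapply(bundle$entries, function(r) paste0(r$resource_type, "/", r$id),
                    character(1))
  refs <- unique(unlist(lapply(bundle$entries, function(r) {
    c(.collect_references(r$body), .collect_references(lapply(r$extension, `[[`, "value")))
  })))
  setdiff(refs, present)
}

#' Resolve a "ResourceType/id" reference inside a bundle
#' @param bundle A \code{fhir_bundle}.
#' @param reference Reference string.
#' @return The referenced \code{fhir_resource}, or NULL.
#' @export
resolve_reference <- function(bundle, reference) {
  for (r in bundle$entries) {
    if (paste0(r$resource_type, "/", r$id) == reference) return(r)
  }
  NULL
}

#' @export
print.fhir_resource <- function(x, ...) {
  cat("<FHIR ", x$resource_type, "> id=", x$id, " version=", x$version_id,
      " fields=", length(x$body), " extensions=", length(x$extension), "\n", sep = "")
  invisible(x)
}

#' @export
print.fhir_bundle <- function(x, ...) {
  cat("<FHIR Bundle: ", x$bundle_type, "> ", length(x$entries), " entries: ",
      paste(vapply(x$entries, `[[`, character(1), "resource_type"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
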