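# In-memory FHIR-style resource repository exposing the server operation set:
# create, history, read, search, update — with an authorization stub standing
# in for OAuth 2.0 access tokens and a soft delete hidden behind a config
# switch. Storage is an environment keyed by "ResourceType/id"; history is
# append-only and version ids increase strictly by one.

#' Create an in-memory FHIR repository
#'
#' @param enable_auth When TRUE every operation requires a token authorized by
#'   [authorize()] (off by default).
#' @param allow_delete Expose soft delete (off by default).
#' @param snapshot_path Optional path for JSON-lines snapshots via
#'   [repo_snapshot()].
#' @return An object of class \code{fhir_repository}.
#' @export
fhir_repository <- function(enable_auth = FALSE, allow_delete = FALSE,
                            snapshot_path = NULL) {
  repo <- new.env(parent = emptyenv())
  repo$store <- new.env(parent = emptyenv())
  repo$enable_auth <- enable_auth
  repo$allow_delete <- allow_delete
  repo$snapshot_path <- snapshot_path
  repo$clock <- 0L
  class(repo) <- "fhir_repository"
  repo
}

# static token table standing in for OAuth 2.0 access-token scopes
.AUTH_TABLE <- list(
  "token-read" = c("read", "search", "history"),
  "token-write" = c("create", "update", "read", "search", "history"),
  "token-admin" = c("create", "update", "read", "search", "history", "delete"))

#' Authorize an operation for an access token
#'
#' Deterministic token-table stub: tokens map to permitted operation sets;
#' unknown tokens are denied.
#'
#' @param token Opaque token string.
#' @param operation One of "create", "read", "update", "history", "search",
#'   "delete".
#' @return TRUE (allow) or FALSE (deny).
#' @export
authorize <- function(token, operation) {
  ops <- .AUTH_TABLE[[token %||% ""]]
  !is.null(ops) && operation %in% ops
}

.check_auth <- function(repo, operation, token) {
  if (isTRUE(repo$enable_auth) && !authorize(token, operation)) {
    stop("operation '", operation, "' denied for the supplied token")
  }
}

.key <- function(type, id) paste0(type, "/", id)

.deep_copy <- function(resource) unserialize(serialize(resource, NULL))

#' Store a resource (or unroll a bundle)
#'
#' @param repo A \code{fhir_repository}.
#' @param resource A \code{fhir_resource}, or a \code{fhir_bundle} whose
#'   entries are stored one by one (transaction unrolling).
#' @param token Access token (checked only when auth is enabled).
#' @return Character vector of stored "ResourceType/id" keys.
#' @export
repo_create <- function(repo, resource, token = NULL) {
  .check_auth(repo, "create", token)
  if (inherits(resource, "fhir_bundle")) {
    return(vapply(resource$entries, function(r) repo_create(repo, r, token),
                  character(1)))
  }
  stopifnot(inherits(resource, "fhir_resource"))
  key <- .key(resource$resource_type, resource$id)
  if (!is.null(repo$store[[key]]) && !isTRUE(repo$store[[key]]$deleted)) {
    stop("conflict: resource ", key, " already exists")
  }
  resource$version_id <- 1
  repo$clock <- repo$clock + 1L
  repo$store[[key]] <- list(resource = .deep_copy(resource),
                            history = list(.deep_copy(resource)),
                            received_at = repo$clock, deleted = FALSE)
  key
}

.fetch <- function(repo, type, id) {
  rec <- repo$store[[.key(type, id)]]
  if (is.null(rec) || isTRUE(rec$deleted)) {
    stop("not found: ", .key(type, id))
  }
  rec
}

#' Read the latest version of a resource
#' @inheritParams repo_create
#' @param type,id Resource type and logical id.
#' @return A deep copy of the stored \code{fhir_resource}.
#' @export
repo_read <- function(repo, type, id, token = NULL) {
  .check_auth(repo, "read", token)
  .deep_copy(.fetch(repo, type, id)$resource)
}

#' Update a resource, incrementing its version by exactly one
#' @inheritParams repo_read
#' @param resource The new resource content.
#' @return The new version id.
#' @export
repo_update <- function(repo, type, id, resource, token = NULL) {
  .check_auth(repo, "update", token)
  rec <- .fetch(repo, type, id)
  resource$resource_type <- type
  resource$id <- id
  resource$version_id <- rec$resource$version_id + 1
  rec$resource <- .deep_copy(resource)
  rec$history <- c(rec$history, list(.deep_copy(resource)))
  repo$store[[.key(type, id)]] <- rec
  resource$version_id
}

#' Version history of a resource, oldest first
#' @inheritParams repo_read
#' @return List of \code{fhir_resource} versions.
#' @export
repo_history <- function(repo, type, id, token = NULL) {
  .check_auth(repo, "history", token)
  lapply(.fetch(repo, type, id)$history, .deep_copy)
}

#' Soft-delete a resource (only when the repository allows it)
#' @inheritParams repo_read
#' @export
repo_delete <- function(repo, type, id, token = NULL) {
  if (!isTRUE(repo$allow_delete)) {
    stop("delete is not enabled on this repository")
  }
  .check_auth(repo, "delete", token)
  rec <- .fetch(repo, type, id)
  rec$deleted <- TRUE
  repo$store[[.key(type, id)]] <- rec
  invisible(TRUE)
}

.SEARCH_PARAMS <- c("subject", "code", "gene", "date_from", "date_to")

.matches <- function(resource, params) {
  for (p in names(params)) {
    want <- params[[p]]
    ok <- switch(p,
      subject = {
        ref <- resource$body$subject
        !is.null(ref) && identical(ref$reference, want)
      },
      code = {
        code <- resource$body$code
        if (is.list(code)) identical(code$text, want) else identical(code, want)
      },
      gene = {
        vals <- get_extension_values(resource, .ext_url("observation-geneticsGene"))
        any(vapply(vals, identical, logical(1), want))
      },
      date_from = {
        d <- resource$body$effectiveDateTime
        !is.null(d) && d >= want
      },
      date_to = {
        d <- resource$body$effectiveDateTime
        !is.null(d) && d <= want
      })
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

#' Search latest versions of a type
#'
#' All filters combine with AND semantics; the result set is by construction
#' identical to a linear scan over the latest versions.
#'
#' @inheritParams repo_read
#' @param params Named list of filters; supported keys: \code{subject}
#'   ("Patient/id" reference), \code{code}, \code{gene} (genetics-gene
#'   extension value), \code{date_from}/\code{date_to} (effectiveDateTime
#'   bounds, inclusive).
#' @return A collection \code{fhir_bundle} of matches (stored order).
#' @export
repo_search <- function(repo, type, params = list(), token = NULL) {
  .check_auth(repo, "search", token)
  bad <- setdiff(names(params), .SEARCH_PARAMS)
  if (length(bad) > 0) {
    stop("unsupported search parameter(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(.SEARCH_PARAMS, collapse = ", "))
  }
  keys <- ls(repo$store)
  recs <- lapply(keys, function(k) repo$store[[k]])
  keep <- vapply(recs, function(rec) {
    !isTRUE(rec$deleted) && rec$resource$resource_type == type &&
      .matches(rec$resource, params)
  }, logical(1))
  recs <- recs[keep]
  recs <- recs[order(vapply(recs, `[[`, integer(1), "received_at"))]
  fhir_bundle(lapply(recs, function(rec) .deep_copy(rec$resource)))
}

#' Snapshot the repository to a JSON-lines file
#' @inheritParams repo_read
#' @param path Target path (default the repository's configured path).
#' @export
repo_snapshot <- function(repo, path = repo$snapshot_path) {
  stopifnot(!is.null(path))
  keys <- ls(repo$store)
  lines <- vapply(keys, function(k) {
    to_json(repo$store[[k]]$resource, pretty = FALSE)
  }, character(1))
  writeLines(sub("\n$", "", lines), path)
  invisible(path)
}

#' @export
print.fhir_repository <- function(x, ...) {
  keys <- ls(x$store)
  cat("<fhir_repository> ", length(keys), " resources",
      if (isTRUE(x$enable_auth)) " (auth enabled)", "\n", sep = "")
  invisible(x)
}
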