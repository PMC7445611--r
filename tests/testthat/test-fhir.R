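test_that("resource construction enforces the supported type set", {
  p <- make_resource("Patient", list(birthDate = "1947-04-29"))
  expect_s3_class(p, "fhir_resource")
  expect_equal(p$body$birthDate, "1947-04-29")
  expect_equal(p$version_id, 1)

  empty <- make_resource("Observation")
  expect_equal(empty$version_id, 1)
  expect_length(empty$body, 0)

  expect_error(make_resource("Appointment"), "supported")
})

test_that("extensions require absolute urls and preserve repetition order", {
  url <- paste0(SEQREPORT_EXTENSION_BASE, "observation-geneticsGene")
  obs <- make_resource("Observation", id = "o1")
  obs <- add_extension(obs, url, "BRAF")
  expect_equal(get_extension_values(obs, url)[[1]], "BRAF")
  obs <- add_extension(obs, url, "KRAS")
  expect_equal(unlist(get_extension_values(obs, url)), c("BRAF", "KRAS"))
  expect_error(add_extension(obs, "ethnicity", "2040-4"), "absolute")
})

test_that("JSON parsing requires a resourceType and reports malformed input", {
  p <- from_json('{"resourceType":"Patient","birthDate":"1947-04-29"}')
  expect_equal(p$resource_type, "Patient")
  expect_equal(p$body$birthDate, "1947-04-29")
  expect_error(from_json('{"x":1}'), "resourceType")
  expect_error(from_json('{"resourceType":'), "malformed JSON")
})

test_that("JSON round trip is the identity on randomized resources", {
  set.seed(20260901)
  rand_value <- function(depth = 0) {
    k <- sample.int(if (depth < 2) 4 else 2, 1)
    switch(k,
           paste(sample(letters, 6), collapse = ""),
           round(stats::runif(1, 0, 1e6), 3),
           stats::setNames(lapply(1:2, function(i) rand_value(depth + 1)),
                           paste0("f", sample.int(1000, 2))),
           lapply(1:2, function(i) rand_value(depth + 1)))
  }
  for (i in 1:25) {
    type <- sample(FHIR_RESOURCE_TYPES, 1)
    body <- stats::setNames(lapply(1:3, function(j) rand_value()),
                            paste0("el", sample.int(1000, 3)))
    res <- make_resource(type, body, id = paste0("r", i))
    if (i %% 2 == 0) {
      res <- add_extension(res, paste0(SEQREPORT_EXTENSION_BASE, "observation-geneticsGene"),
                           paste(sample(LETTERS, 4), collapse = ""))
      res <- add_extension(res, paste0(SEQREPORT_EXTENSION_BASE, "molecularsequence-qcMetrics"),
                           list(MeanDepth = round(stats::runif(1, 1, 999)),
                                Uniformity = round(stats::runif(1), 3)))
    }
    expect_equal(from_json(to_json(res)), res)
  }
  # bundles round-trip too
  b <- fhir_bundle(list(make_resource("Patient", list(name = "A"), id = "p1"),
                        make_resource("Observation",
                                      list(subject = fhir_reference("Patient/p1")),
                                      id = "o1")))
  expect_equal(from_json(to_json(b)), b)
})

test_that("bundle reference validation flags dangling references only", {
  p <- make_resource("Patient", list(name = "A"), id = "p1")
  o <- make_resource("Observation", list(subject = fhir_reference("Patient/p1")),
                     id = "o1")
  dr <- make_resource("DiagnosticReport",
                      list(result = list(fhir_reference("Observation/o1"))),
                      id = "d1")
  expect_length(validate_bundle_refs(fhir_bundle(list(p, o, dr))), 0)

  bad <- make_resource("DiagnosticReport",
                       list(result = list(fhir_reference("Observation/missing"))),
                       id = "d2")
  expect_equal(validate_bundle_refs(fhir_bundle(list(bad))), "Observation/missing")
  expect_length(validate_bundle_refs(fhir_bundle(list())), 0)
})
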