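test_that("the worked-example bundle carries the published variant content", {
  bundle <- build_bundle(worked_example())
  obs <- Filter(function(r) r$resource_type == "Observation", bundle$entries)[[1]]
  gv <- function(name) {
    get_extension_values(obs, paste0(SEQREPORT_EXTENSION_BASE, name))[[1]]
  }
  expect_equal(gv("observation-geneticsGene"), "BRAF")
  expect_equal(gv("observation-geneticsGeneId"), "HGNC:1097")
  expect_equal(gv("observation-geneticsDNAVariantId"), "COSM476")
  expect_equal(gv("observation-geneticsDNASequenceVariantName"), "c.1799T > A_p.V600E")
  cls <- gv("observation-classificationVariants")
  expect_equal(cls$Tier, "Tier 1")
  expect_equal(cls$Pathogeny, "Pathogenic")
  expect_equal(cls$ClinicalRelavance, "Identified")

  dr <- Filter(function(r) r$resource_type == "DiagnosticReport", bundle$entries)[[1]]
  expect_equal(dr$body$result[[1]]$reference, paste0("Observation/", obs$id))
  expect_length(validate_bundle_refs(bundle), 0)
})

test_that("extraction inverts building on the worked example", {
  we <- worked_example()
  expect_equal(extract_report(build_bundle(we)), we, ignore_attr = TRUE)
})

test_that("a report with zero variants builds a bundle without variant observations", {
  we <- worked_example()
  we$variants <- list()
  expect_equal(nrow(validate_report(we)), 0)
  bundle <- build_bundle(we)
  expect_length(Filter(function(r) r$resource_type == "Observation", bundle$entries), 0)
  expect_length(Filter(function(r) r$resource_type == "DiagnosticReport", bundle$entries), 1)
  back <- extract_report(bundle)
  expect_equal(back, we, ignore_attr = TRUE)
})

test_that("building refuses a non-conformant report with its issue list", {
  we <- worked_example()
  we$subject$name <- NULL
  expect_error(build_bundle(we), "missing-required subject.name")
})

test_that("unknown extensions are collected, not dropped", {
  bundle <- build_bundle(worked_example())
  idx <- which(vapply(bundle$entries, function(r) r$resource_type, character(1)) ==
                 "Observation")[1]
  bundle$entries[[idx]] <- add_extension(
    bundle$entries[[idx]], "https://other.example.org/fhir/StructureDefinition/custom",
    "x")
  back <- extract_report(bundle)
  unmapped <- attr(back, "unmapped")
  expect_length(unmapped, 1)
  expect_match(unmapped[[1]]$url, "custom")
  expect_equal(back, worked_example(), ignore_attr = TRUE)
})

test_that("extraction requires a DiagnosticReport", {
  b <- fhir_bundle(list(make_resource("Patient", list(name = "A"), id = "p1")))
  expect_error(extract_report(b), "no DiagnosticReport")
})

test_that("round-trip identity and reference closure hold over a seeded corpus", {
  cfg <- generator_config(seed = 301, n_reports = 30,
                          include_research_block = 0.6, missingness = 0.2)
  reports <- generate_reports(cfg)
  for (r in reports) {
    bundle <- build_bundle(r)
    expect_length(validate_bundle_refs(bundle), 0)
    expect_equal(extract_report(bundle), r, ignore_attr = TRUE)
  }
})

test_that("every populated element lands at its mapped path (independent walker)", {
  for (r in list(worked_example(), full_report(7), full_report(8))) {
    bundle <- build_bundle(r)
    expect_equal(check_field_placement(r, bundle), character(0))
  }
})

test_that("bundle JSON round-trips through serialization with the report intact", {
  bundle <- build_bundle(full_report(11))
  bundle2 <- from_json(to_json(bundle))
  expect_equal(bundle2, bundle)
  expect_equal(extract_report(bundle2), extract_report(bundle), ignore_attr = TRUE)
})
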