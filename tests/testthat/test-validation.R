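test_that("the worked example is conformant and an empty report misses all 32", {
  expect_equal(nrow(validate_report(worked_example())), 0)
  issues <- validate_report(sequencing_report())
  expect_equal(nrow(issues), 32)
  expect_true(all(issues$code == "missing-required"))
  expect_true(all(issues$severity == "error"))
  # independent oracle: the missing set is exactly the required registry ids
  reg <- load_element_registry()
  expect_setequal(issues$element_id, reg$element_id[reg$field_class == "required"])
})

test_that("missing-required equals the brute-force set difference on partial reports", {
  # independent element -> (section, field) map, maintained by hand on purpose
  loc <- list(
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
  set.seed(404)
  for (k in c(3, 8, 14)) {
    we <- worked_example()
    drop <- sample(c(names(loc), "treatment.recommended_treatment"), k)
    for (id in drop) {
      if (id == "treatment.recommended_treatment") {
        we$treatments <- NULL
      } else {
        p <- loc[[id]]
        we[[p[1]]][[p[2]]] <- NULL
      }
    }
    issues <- validate_report(we)
    missing <- issues$element_id[issues$code == "missing-required"]
    expect_setequal(missing, drop)
  }
})

test_that("out-of-set and malformed codes are flagged on the offending element", {
  we <- worked_example()
  we$subject$sex_code <- "7"
  issues <- validate_report(we)
  expect_equal(nrow(issues), 1)
  expect_equal(issues$element_id, "subject.sex")
  expect_equal(issues$code, "bad-code")

  we2 <- worked_example()
  we2$subject$birth_date <- "29/04/1947"
  issues2 <- validate_report(we2)
  expect_true(any(issues2$element_id == "subject.birth_date" &
                    issues2$code == "bad-format"))
})

test_that("code validation applies the terminology bindings", {
  expect_true(validate_code("HGNC", "HGNC:1097"))
  expect_true(validate_code("ISO 8601", "1947-04-29"))
  bad <- validate_code("ISO 8601", "29/04/1947")
  expect_equal(bad$code, "bad-format")
  expect_true(validate_code("HL7 v3 race", "2040-4"))
  expect_equal(validate_code("HL7 v3 race", "Korean")$code, "bad-format")
  expect_equal(validate_code("HGNC", "BRAF")$code, "bad-format")
  expect_error(validate_code("SNOMED", "12345"), "unknown binding")
})

test_that("adding a valid field never increases the issue count", {
  we <- worked_example()
  fields <- list(
    function(r) { r$subject <- NULL; r },
    function(r) { r$order$performing_laboratory <- NULL; r },
    function(r) { r$treatments <- NULL; r })
  stripped <- Reduce(function(r, f) f(r), fields, worked_example())
  n_prev <- nrow(validate_report(stripped))
  # restore fields one by one; the issue count must be non-increasing
  stripped$treatments <- we$treatments
  n1 <- nrow(validate_report(stripped))
  expect_lte(n1, n_prev)
  stripped$order$performing_laboratory <- we$order$performing_laboratory
  n2 <- nrow(validate_report(stripped))
  expect_lte(n2, n1)
  stripped$subject <- we$subject
  n3 <- nrow(validate_report(stripped))
  expect_lte(n3, n2)
  expect_equal(n3, 0)
})

test_that("coverage of a fully populated bundle reproduces the mapping statistics", {
  bundle <- build_bundle(full_report(55))
  expect_identical(coverage_summary(bundle), mapping_statistics())
})

test_that("coverage of empty and worked-example bundles behaves as expected", {
  empty <- coverage_summary(fhir_bundle(list()))
  expect_true(all(empty$required$elements == 0) && empty$grand_total == 0)

  we_cov <- coverage_summary(build_bundle(worked_example()))
  req_total <- we_cov$required[we_cov$required$resource_type == "Total", ]
  opt_total <- we_cov$optional[we_cov$optional$resource_type == "Total", ]
  expect_gt(req_total$elements + req_total$extensions, 0)
  expect_equal(opt_total$elements + opt_total$extensions, 0)
})
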