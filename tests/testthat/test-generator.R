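test_that("the generator is deterministic under its seed", {
  cfg <- generator_config(seed = 42, n_reports = 5, include_research_block = 0.7,
                          missingness = 0.3)
  expect_identical(generate_reports(cfg), generate_reports(cfg))
  # and leaves the session RNG untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_reports(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a missingness-0 corpus validates cleanly", {
  cfg <- generator_config(seed = 9, n_reports = 50, include_research_block = 0.5,
                          missingness = 0)
  reports <- generate_reports(cfg)
  expect_length(reports, 50)
  for (r in reports) {
    issues <- validate_report(r)
    expect_equal(sum(issues$severity == "error"), 0)
  }
})

test_that("required-field corruption yields at least one error per report", {
  cfg <- generator_config(seed = 10, n_reports = 10, corrupt_required = TRUE)
  for (r in generate_reports(cfg)) {
    expect_gt(sum(validate_report(r)$severity == "error"), 0)
  }
})

test_that("every generated code belongs to its declared value set", {
  cfg <- generator_config(seed = 11, n_reports = 20, include_research_block = 1,
                          missingness = 0)
  for (r in generate_reports(cfg)) {
    expect_true(r$subject$sex_code %in% value_set("sex_iso22220")$code)
    expect_true(r$subject$ethnicity_code %in% value_set("race_hl7v3")$code)
    for (v in r$variants) {
      expect_true(v$classification$tier %in% value_set("tier")$code)
      expect_true(v$classification$pathogeny %in% value_set("pathogeny")$code)
      expect_true(v$classification$clinical_relevance %in%
                    value_set("clinical_relevance")$code)
      expect_true(v$gene_symbol %in% hgnc_micro_list()$symbol)
    }
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_reports = 0), "positive")
  expect_error(generator_config(variants_min = 3, variants_max = 1), "range")
  expect_error(generator_config(missingness = 1.5), "0, 1")
})

test_that("generate -> validate -> build -> store -> search -> extract -> render completes cleanly", {
  cfg <- generator_config(seed = 12, n_reports = 5, include_research_block = 1,
                          missingness = 0)
  repo <- fhir_repository()
  reports <- generate_reports(cfg)
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    expect_equal(sum(validate_report(r)$severity == "error"), 0)
    bundle <- build_bundle(r, id_prefix = sprintf("rep%d-", i))
    keys <- repo_create(repo, bundle)
    expect_length(keys, length(bundle$entries))
    found <- repo_search(repo, "DiagnosticReport")
    expect_gte(length(found$entries), i)
    back <- extract_report(bundle)
    expect_equal(back, r, ignore_attr = TRUE)
    summary <- render_summary(bundle)
    expect_match(summary$text, "VARIANT RESULTS")
  }
})
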