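test_that("published example elements map to the printed FHIR paths", {
  gene <- map_element("genetic_variation.gene_symbol")
  expect_equal(gene$resource_type, "Observation")
  expect_equal(gene$fhir_path, "Observation.extension(observation-geneticsGene)")
  expect_equal(gene$mapping_kind, "extension")

  eth <- map_element("subject.ethnicity")
  expect_equal(eth$resource_type, "DiagnosticReport")
  expect_equal(eth$fhir_path, "DiagnosticReport.subject(patient).extension(ethnicity)")
  expect_equal(eth$mapping_kind, "extension")

  nm <- map_element("subject.name")
  expect_equal(nm$fhir_path, "DiagnosticReport.subject(patient)")
  expect_equal(nm$mapping_kind, "reuse")

  expect_error(map_element("no.such.element"), "unknown element_id")
})

test_that("mapping table satisfies its structural invariants", {
  map <- load_mapping_table()
  expect_true(all(mapply(startsWith, map$fhir_path, map$resource_type)))
  expect_equal(grepl("extension(", map$fhir_path, fixed = TRUE),
               map$mapping_kind == "extension")
  expect_equal(nzchar(map$extension_url), map$mapping_kind == "extension")
  # field-class slots live only on their five resource types
  expect_true(all(map$resource_type[map$field_class == "required"] %in%
                    PUBLISHED_REQUIRED_COUNTS$resource_type))
  expect_true(all(map$resource_type[map$field_class == "optional"] %in%
                    PUBLISHED_OPTIONAL_COUNTS$resource_type))
  # total and single-valued over the registry: every element, one primary slot
  reg <- load_element_registry()
  expect_setequal(unique(map$element_id), reg$element_id)
  primaries <- tapply(map$primary, map$element_id, sum)
  expect_true(all(primaries == 1))
})

test_that("mapping statistics reproduce the published per-resource counts", {
  st <- mapping_statistics()
  expect_equal(st$required[1:5, ], PUBLISHED_REQUIRED_COUNTS, ignore_attr = TRUE)
  expect_equal(st$optional[1:5, ], PUBLISHED_OPTIONAL_COUNTS, ignore_attr = TRUE)
  expect_equal(st$required$elements[6], 26)    # reused, required
  expect_equal(st$required$extensions[6], 15)  # extended, required
  expect_equal(st$optional$elements[6], 28)
  expect_equal(st$optional$extensions[6], 21)
  expect_equal(st$grand_total, 90)
})

test_that("statistics on an emptied table are all zeros", {
  map <- load_mapping_table()
  st <- mapping_statistics(map[0, , drop = FALSE])
  expect_true(all(st$required$elements == 0) && all(st$required$extensions == 0))
  expect_true(all(st$optional$elements == 0) && all(st$optional$extensions == 0))
  expect_equal(st$grand_total, 0)
})

test_that("extension registry covers every extension slot and the classification triple", {
  defs <- extension_definitions()
  expect_false(any(duplicated(defs$url)))
  expect_true("observation-geneticsDNAVariantId" %in% defs$name)
  expect_equal(defs$host_resource[defs$name == "observation-geneticsDNAVariantId"],
               "Observation")
  subs <- c("observation-classificationVariants.Tier",
            "observation-classificationVariants.Pathogeny",
            "observation-classificationVariants.ClinicalRelavance")
  expect_true(all(subs %in% defs$name))
  map <- load_mapping_table()
  ext_rows <- map[map$mapping_kind == "extension", ]
  expect_equal(nrow(ext_rows), 36)  # 15 required + 21 optional usages
  expect_true(all(ext_rows$extension_url %in% defs$url))
})

test_that("mapping export and reimport are lossless", {
  map <- load_mapping_table()
  sorted <- map[order(map$field_class, map$resource_type, map$element_id), ]
  rownames(sorted) <- NULL
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    export_mapping_table(path)
    back <- import_mapping_table(path)
    expect_equal(back, sorted, ignore_attr = TRUE)
  }
})
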