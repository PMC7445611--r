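test_that("registry carries 32 required and 29 optional elements with unique ids", {
  reg <- load_element_registry()
  expect_equal(sum(reg$field_class == "required"), 32)
  expect_equal(sum(reg$field_class == "optional"), 29)
  expect_equal(nrow(reg), 61)
  expect_false(any(duplicated(reg$element_id)))
  expect_true(all(reg$provenance %in% c("paper", "reconstructed")))
  # loading twice yields deeply equal registries
  expect_identical(load_element_registry(), reg)
})

test_that("elements enumerable from the published mapping example carry paper provenance", {
  table1_ids <- c("subject.identifier", "subject.name", "subject.birth_date",
                  "subject.sex", "subject.ethnicity",
                  "genetic_variation.gene_symbol",
                  "genetic_variation.variant_notation",
                  "genetic_variation.variant_effect",
                  "genetic_variation.variant_db_id")
  reg <- load_element_registry()
  prov <- reg$provenance[match(table1_ids, reg$element_id)]
  expect_true(all(prov == "paper"))
})

test_that("element lookup returns the bound metadata standard", {
  expect_equal(element_lookup("subject.birth_date")$metadata_standard, "ISO 8601")
  expect_equal(element_lookup("subject.sex")$metadata_standard, "ISO/TS 22220:2011")
  gene <- element_lookup("genetic_variation.gene_symbol")
  expect_equal(gene$metadata_standard, "HGNC")
  expect_equal(gene$field_class, "required")
  err <- tryCatch(element_lookup("nonexistent.path"), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "nearest matches")
})

test_that("controlled value sets have the defined codes", {
  path <- value_set("pathogeny")
  expect_equal(nrow(path), 5)
  expect_equal(path$code[1], "Pathogenic")
  expect_setequal(path$code, c("Pathogenic", "Likely pathogenic",
                               "Unknown significance", "Likely benign", "Benign"))
  rel <- value_set("clinical_relevance")
  expect_equal(nrow(rel), 4)
  expect_setequal(rel$code, c("Identified", "Likely identified", "Uncertain",
                              "Not identified"))
  sex <- value_set("sex_iso22220")
  expect_equal(sex$display[sex$code == "1"], "Male")
  expect_error(value_set("hla_loci"), "unknown value set")
})

test_that("registry export writes the documented columns and survives reimport", {
  csv <- tempfile(fileext = ".csv")
  export_registry(csv)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(names(back), c("element_id", "display_name", "field_class",
                              "section", "metadata_standard", "provenance"))
  expect_equal(as.vector(table(back$field_class)[c("required", "optional")]),
               c(32L, 29L))
  json <- tempfile(fileext = ".json")
  export_registry(json)
  back2 <- jsonlite::fromJSON(json)
  expect_equal(nrow(back2), 61)
})
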