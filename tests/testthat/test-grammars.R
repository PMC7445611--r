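test_that("classification grammar parses the printed triple form", {
  t1 <- parse_classification("Tier 1 (Pathogenic, Identified)")
  expect_equal(t1$tier, "Tier 1")
  expect_equal(t1$pathogeny, "Pathogenic")
  expect_equal(t1$clinical_relevance, "Identified")

  t3 <- parse_classification("Tier 3 (Unknown significance, Uncertain)")
  expect_equal(t3$tier, "Tier 3")
  expect_equal(t3$pathogeny, "Unknown significance")
  expect_equal(t3$clinical_relevance, "Uncertain")

  # whitespace tolerance
  expect_equal(parse_classification("  Tier 2 ( Likely pathogenic ,  Likely identified ) "),
               classification_triple("Tier 2", "Likely pathogenic", "Likely identified"))

  expect_error(parse_classification("Pathogenic"), "cannot parse")
  expect_error(parse_classification("Tier 1 (Bad, Identified)"),
               "pathogeny component")
})

test_that("classification formatting inverts parsing over all valid triples", {
  expect_equal(format_classification(
    classification_triple("Tier 1", "Pathogenic", "Identified")),
    "Tier 1 (Pathogenic, Identified)")
  for (tier in value_set("tier")$code) {
    for (path in value_set("pathogeny")$code) {
      for (rel in value_set("clinical_relevance")$code) {
        triple <- classification_triple(tier, path, rel)
        expect_equal(parse_classification(format_classification(triple)), triple)
      }
    }
  }
  bad <- classification_triple("Tier 1", "Bad", "Identified", validate = FALSE)
  expect_error(format_classification(bad), "pathogeny")
})

test_that("variant-notation grammar handles the report dialect", {
  both <- parse_variant_notation("c.1799T > A_p.V600E")
  expect_equal(both$cdna_change, "c.1799T>A")
  expect_equal(both$protein_change, "p.V600E")

  cdna_only <- parse_variant_notation("c.35G>A")
  expect_equal(cdna_only$cdna_change, "c.35G>A")
  expect_null(cdna_only$protein_change)

  genomic <- parse_variant_notation("g.140453136A > T")
  expect_equal(genomic$cdna_change, "g.140453136A>T")

  expect_error(parse_variant_notation("V600E"), "prefix|c\\.")
  expect_error(parse_variant_notation("c.35G>A_V600E"), "p\\.")
})

test_that("variant records derive normalized changes from the raw notation", {
  v <- variant_record(gene_hgnc_id = "HGNC:1097", gene_symbol = "BRAF",
                      hgvs_notation = "c.1799T > A_p.V600E")
  expect_equal(v$hgvs_notation, "c.1799T > A_p.V600E")  # verbatim display form
  expect_equal(v$cdna_change, "c.1799T>A")
  expect_equal(v$protein_change, "p.V600E")
})

test_that("report documents survive a write/read cycle", {
  we <- worked_example()
  path <- tempfile(fileext = ".json")
  write_report(we, path)
  expect_equal(read_report(path), we)

  full <- full_report()
  path2 <- tempfile(fileext = ".json")
  write_report(full, path2)
  expect_equal(read_report(path2), full)

  # YAML is accepted on input
  ypath <- tempfile(fileext = ".yaml")
  yaml::write_yaml(jsonlite::fromJSON(path, simplifyVector = FALSE), ypath)
  expect_equal(read_report(ypath), we)
})
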