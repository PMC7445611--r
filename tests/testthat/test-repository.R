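test_that("create/read round-trips a deep-equal copy at version 1", {
  repo <- fhir_repository()
  p <- make_resource("Patient", list(name = "A", birthDate = "1947-04-29"),
                     id = "p1")
  key <- repo_create(repo, p)
  expect_equal(key, "Patient/p1")
  back <- repo_read(repo, "Patient", "p1")
  expect_equal(back, p)
  expect_equal(back$version_id, 1)
  expect_error(repo_create(repo, p), "conflict")
  expect_error(repo_read(repo, "Patient", "nope"), "not found")
})

test_that("creating a bundle unrolls into one id per entry", {
  repo <- fhir_repository()
  bundle <- build_bundle(worked_example())
  keys <- repo_create(repo, bundle)
  expect_length(keys, length(bundle$entries))
  expect_equal(repo_read(repo, "Patient", "patient-1")$body$name, "Gildong Hong")
})

test_that("update increments versions by one and history is append-only, oldest first", {
  repo <- fhir_repository()
  repo_create(repo, make_resource("Observation", list(status = "preliminary"),
                                  id = "o1"))
  v2 <- repo_update(repo, "Observation", "o1",
                    make_resource("Observation", list(status = "final"), id = "o1"))
  expect_equal(v2, 2)
  expect_equal(repo_read(repo, "Observation", "o1")$body$status, "final")
  hist <- repo_history(repo, "Observation", "o1")
  expect_length(hist, 2)
  expect_equal(vapply(hist, `[[`, numeric(1), "version_id"), c(1, 2))
  expect_equal(hist[[1]]$body$status, "preliminary")
})

test_that("search filters with AND semantics over latest versions", {
  repo <- fhir_repository()
  gene_url <- paste0(SEQREPORT_EXTENSION_BASE, "observation-geneticsGene")
  for (i in 1:3) {
    obs <- make_resource("Observation",
                         list(subject = fhir_reference("Patient/p1"),
                              effectiveDateTime = sprintf("2026-01-0%d", i)),
                         id = paste0("a", i))
    repo_create(repo, add_extension(obs, gene_url, "BRAF"))
  }
  for (i in 1:2) {
    repo_create(repo, make_resource(
      "Observation", list(subject = fhir_reference("Patient/p2")),
      id = paste0("b", i)))
  }
  expect_length(repo_search(repo, "Observation",
                            list(subject = "Patient/p1"))$entries, 3)
  expect_length(repo_search(repo, "Observation")$entries, 5)
  expect_length(repo_search(repo, "Observation", list(gene = "BRAF"))$entries, 3)
  expect_length(repo_search(repo, "Observation",
                            list(subject = "Patient/p1",
                                 date_from = "2026-01-02"))$entries, 2)
  expect_error(repo_search(repo, "Observation", list(frobnicate = "x")),
               "unsupported search parameter")
})

test_that("search equals a brute-force linear scan on randomized stores", {
  set.seed(777)
  gene_url <- paste0(SEQREPORT_EXTENSION_BASE, "observation-geneticsGene")
  for (trial in 1:5) {
    repo <- fhir_repository()
    all_res <- list()
    for (i in 1:40) {
      subj <- paste0("Patient/p", sample.int(4, 1))
      gene <- sample(c("BRAF", "KRAS", "EGFR"), 1)
      date <- sprintf("2026-%02d-%02d", sample.int(12, 1), sample.int(28, 1))
      obs <- make_resource("Observation",
                           list(subject = fhir_reference(subj),
                                effectiveDateTime = date),
                           id = paste0("t", trial, "o", i))
      obs <- add_extension(obs, gene_url, gene)
      repo_create(repo, obs)
      all_res[[i]] <- list(res = obs, subj = subj, gene = gene, date = date)
    }
    params <- list(subject = paste0("Patient/p", sample.int(4, 1)),
                   gene = sample(c("BRAF", "KRAS", "EGFR"), 1),
                   date_from = "2026-04-01")
    got <- repo_search(repo, "Observation", params)
    # independent oracle: plain linear scan over what was inserted
    want <- Filter(function(x) {
      x$subj == params$subject && x$gene == params$gene &&
        x$date >= params$date_from
    }, all_res)
    expect_setequal(vapply(got$entries, `[[`, character(1), "id"),
                    vapply(want, function(x) x$res$id, character(1)))
  }
})

test_that("authorization stub allows by token scope and denies unknown tokens", {
  expect_true(authorize("token-read", "read"))
  expect_false(authorize("token-read", "update"))
  expect_true(authorize("token-write", "update"))
  expect_false(authorize("made-up-token", "read"))

  repo <- fhir_repository(enable_auth = TRUE)
  p <- make_resource("Patient", list(name = "A"), id = "p1")
  expect_error(repo_create(repo, p, token = "token-read"), "denied")
  repo_create(repo, p, token = "token-write")
  expect_equal(repo_read(repo, "Patient", "p1", token = "token-read")$body$name, "A")
})

test_that("delete is hidden behind the repository configuration switch", {
  repo <- fhir_repository()
  repo_create(repo, make_resource("Patient", list(name = "A"), id = "p1"))
  expect_error(repo_delete(repo, "Patient", "p1"), "not enabled")

  repo2 <- fhir_repository(allow_delete = TRUE)
  repo_create(repo2, make_resource("Patient", list(name = "A"), id = "p1"))
  repo_delete(repo2, "Patient", "p1")
  expect_error(repo_read(repo2, "Patient", "p1"), "not found")
})
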