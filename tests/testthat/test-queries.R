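test_that("named queries agree with brute-force record filters on a seeded fixture", {
  fx <- generate_fixture(fixture_config(n_parts = 200, seed = 31))
  g <- build_knowledgebase(fx$parts, fx$features)
  m <- fx$manifest

  r1 <- q_parts_by_class(g, "promoter")
  expect_equal(result_part_names(g, r1), oracle_members(m, "promoter"))

  r3 <- q_clean_parts(g, "promoter")
  expect_equal(result_part_names(g, r3), oracle_clean(m, "promoter"))

  r4 <- q_clean_parts(g)
  expect_equal(result_part_names(g, r4), oracle_clean(m))

  r5 <- q_by_status(g, c("Available", "Sent"))
  expect_equal(result_part_names(g, r5),
               oracle_by_status(m, c("Available", "Sent")))

  r6 <- q_conjunctive_classes(g, c("promoter", "sigma70_ecoli_prokaryote_rnap"))
  expect_equal(result_part_names(g, r6),
               oracle_conjunction(m, c("promoter", "sigma70_ecoli_prokaryote_rnap")))

  r7 <- q_conjunctive_classes(g, c("promoter", "positive_regulation",
                                   "negative_regulation"))
  expect_equal(result_part_names(g, r7),
               oracle_conjunction(m, c("promoter", "positive_regulation",
                                       "negative_regulation")))

  rf <- q_dual_regulated_with_features(g)
  expect_equal(result_part_names(g, rf), oracle_dual_with_features(m))
})

test_that("promoter retrieval reaches parts tagged only in subcategories", {
  fx <- generate_fixture(fixture_config(n_parts = 150, seed = 41))
  m <- fx$manifest
  only_sub <- vapply(m$categories, function(cc) {
    "//promoter/constitutive" %in% cc && !"//promoter" %in% cc
  }, logical(1))
  expect_gt(sum(only_sub), 0)  # this seed yields subcategory-only promoters
  g <- build_knowledgebase(fx$parts, fx$features)
  res <- result_part_names(g, q_parts_by_class(g, "promoter"))
  expect_true(all(m$name[only_sub] %in% res))
  # without materialization those parts are invisible to the plain query
  g_off <- build_knowledgebase(fx$parts, fx$features, materialize = FALSE)
  res_off <- result_part_names(g_off, q_parts_by_class(g_off, "promoter"))
  expect_false(any(m$name[only_sub] %in% res_off))
  expect_equal(sort(res_off), oracle_members(m, "promoter", materialize = FALSE))
})

test_that("unknown classes give empty results with a warning", {
  g <- build_knowledgebase(inpaper_fixture(0)$parts)
  expect_warning(res <- q_parts_by_class(g, "zzz"), "not declared")
  expect_equal(nrow(res$rows), 0)
})

test_that("cleaning removes deleted and sequence-less parts and is idempotent", {
  fx <- generate_fixture(fixture_config(n_parts = 10, seed = 55))
  # force a known composition: 10 promoters, 2 deleted, 1 without sequence
  fx$parts$categories <- rep(list("//promoter"), 10)
  fx$parts$status <- c(rep("Available", 8), "Deleted", "Deleted")
  fx$parts$status_raw <- fx$parts$status
  fx$parts$dna_sequence[1] <- ""
  fx$parts$dna_sequence[2:8] <- vapply(rep(50, 7), function(L)
    paste(sample(c("a","c","g","t"), L, TRUE), collapse = ""), character(1))
  g <- build_knowledgebase(fx$parts)
  res <- q_clean_parts(g, "promoter")
  expect_equal(res$distinct_subjects, 7)

  # idempotence: the clean set, rebuilt as its own graph, filters to itself
  keep <- fx$parts$name %in% result_part_names(g, res)
  g2 <- build_knowledgebase(fx$parts[keep, ])
  res2 <- q_clean_parts(g2, "promoter")
  expect_setequal(result_part_names(g2, res2), result_part_names(g, res))

  fx$parts$status <- rep("Deleted", 10); fx$parts$status_raw <- fx$parts$status
  g3 <- build_knowledgebase(fx$parts)
  expect_equal(q_clean_parts(g3, "promoter")$distinct_subjects, 0)
})

test_that("status selection matches the manifest and the empty set gives nothing", {
  fx <- generate_fixture(fixture_config(n_parts = 120, seed = 61))
  g <- build_knowledgebase(fx$parts, fx$features)
  for (statuses in list("Available", c("Available", "Sent"), "Deleted")) {
    expect_equal(result_part_names(g, q_by_status(g, statuses)),
                 oracle_by_status(fx$manifest, statuses))
  }
  expect_equal(nrow(q_by_status(g, character(0))$rows), 0)
})

test_that("conjunctions are contained in every single-class result", {
  fx <- generate_fixture(fixture_config(n_parts = 150, seed = 71))
  g <- build_knowledgebase(fx$parts, fx$features)
  classes <- c("promoter", "positive_regulation", "negative_regulation")
  conj <- result_part_names(g, q_conjunctive_classes(g, classes))
  for (cl in classes) {
    expect_true(all(conj %in% result_part_names(g, q_parts_by_class(g, cl))))
  }
})

test_that("the refinement chain narrows monotonically", {
  for (seed in c(81, 82)) {
    fx <- generate_fixture(fixture_config(n_parts = 200, seed = seed))
    g <- build_knowledgebase(fx$parts, fx$features)
    q1 <- result_part_names(g, q_parts_by_class(g, "promoter"))
    q3 <- result_part_names(g, q_clean_parts(g, "promoter"))
    dual <- result_part_names(g, q_conjunctive_classes(
      g, c("promoter", "positive_regulation", "negative_regulation")))
    dual_feat <- result_part_names(g, q_dual_regulated_with_features(g))
    expect_true(all(q3 %in% q1))
    expect_true(all(dual %in% q1))
    expect_true(all(dual_feat %in% dual))
  }
})

test_that("describe over a class covers the per-part emission additively", {
  fx <- inpaper_fixture(0, seed = 1)
  g <- build_knowledgebase(fx$parts, fx$features)
  desc <- q_describe_class(g, "promoter")
  expect_true(any(desc$predicate == "sbolcore:longDescription" &
                    startsWith(desc$object, "This is the PLL promoter")))
  # union over all parts equals describing the core Part class
  all_desc <- q_describe_class(g, "Part")
  part_subjects <- unique(g$statements$subject[
    g$statements$predicate == "rdf:type" & g$statements$object == "sbolcore:Part"])
  manual <- g$statements[g$statements$subject %in% part_subjects, ]
  expect_true(statements_equal(all_desc, manual))
})

test_that("dual-regulated promoters lacking features are excluded by the join", {
  fx <- inpaper_fixture(0, seed = 1)
  extra <- fx$parts[fx$parts$name == "BBa_I12036", ]
  extra$registry_id <- 77777L
  extra$name <- "BBa_NOFEAT"
  fx$parts <- rbind(fx$parts, extra)
  g <- build_knowledgebase(fx$parts, fx$features)
  res <- q_dual_regulated_with_features(g)
  expect_false("BBa_NOFEAT" %in% res$rows$name)
  dual <- q_conjunctive_classes(g, c("promoter", "positive_regulation",
                                     "negative_regulation"))
  expect_true("BBa_NOFEAT" %in% result_part_names(g, dual))
})

test_that("query results serialize to TSV and SPARQL-results JSON", {
  g <- build_knowledgebase(inpaper_fixture(0)$parts, inpaper_fixture(0)$features)
  res <- q_dual_regulated_with_features(g)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "r.tsv")
  write_query_result(res, tsv, "tsv")
  lines <- readLines(tsv)
  expect_equal(strsplit(lines[1], "\t")[[1]], res$variables)
  expect_equal(length(lines) - 1, nrow(res$rows))
  js <- file.path(dir, "r.json")
  write_query_result(res, js, "json")
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(unlist(parsed$head$vars), res$variables)
  expect_equal(length(parsed$results$bindings), nrow(res$rows))
})
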