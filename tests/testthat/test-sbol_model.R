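test_that("identifier minting is deterministic and shape-valid", {
  a <- mint_id("part", 9598, "BBa_I746365")
  b <- mint_id("part", 9598, "BBa_I746365")
  expect_identical(a, b)
  expect_match(a, "^[A-Za-z][A-Za-z0-9]+$")
  expect_match(a, "9598$")
  expect_false(mint_id("part", 1, "A") == mint_id("part", 2, "A"))
  expect_false(mint_id("part", 1, "A") == mint_id("annotation", 1, "A"))
})

test_that("minted ids are unique across a large random sweep", {
  set.seed(13)
  n <- 10000
  ids <- sample.int(1e6, n)
  names <- sprintf("BBa_%06d", sample.int(1e6, n))
  minted <- mapply(mint_id, registry_id = ids, name = names,
                   MoreArgs = list(kind = "part"))
  expect_equal(length(unique(minted)), n)
})

test_that("the describe example part emits exactly the printed property set", {
  fx <- inpaper_fixture(0, seed = 1)
  rec <- fx$parts[fx$parts$name == "BBa_I746365", ]
  tree <- build_category_tree(unlist(fx$parts$categories))
  st <- part_to_statements(rec, tree, materialize = FALSE)
  subj <- unique(st$subject)
  expect_length(subj, 1)

  types <- st$object[st$predicate == "rdf:type"]
  expect_setequal(types, c("sbolcore:Part", "pr:promoter",
                           "pr:positive_regulation", "pr:forward_direction",
                           "pr:ecoli_prokaryote_chassis",
                           "pr:sigma70_ecoli_prokaryote_rnap"))

  lit <- function(p) st$object[st$predicate == paste0("sbolcore:", p)]
  expect_equal(lit("name"), "BBa_I746365")
  expect_equal(lit("type"), "Regulatory")
  expect_equal(lit("shortDescription"), "PLL promoter from P4 phage")
  expect_match(lit("longDescription"), "^This is the PLL promoter taken from the P4 phage genome")
  expect_equal(lit("author"), "Stefan Milde")
  expect_equal(lit("status"), "Available")
  expect_equal(lit("id"), "9598")
  expect_equal(lit("owner_id"), "2122")
  expect_equal(lit("date"), "9/11/2007")
  expect_match(lit("dnaSequence"), "^cgctttattttgtgaatattt")
})

test_that("a part with no categories still gets its core type and literals", {
  parts <- generate_fixture(fixture_config(n_parts = 1, seed = 2))$parts
  parts$categories <- list(character(0))
  tree <- build_category_tree(list())
  st <- part_to_statements(parts[1, ], tree)
  expect_equal(st$object[st$predicate == "rdf:type"], "sbolcore:Part")
  expect_true("sbolcore:name" %in% st$predicate)
})

test_that("materialization adds exactly the ancestor classes, monotonically", {
  parts <- generate_fixture(fixture_config(n_parts = 1, seed = 2))$parts
  parts$categories <- list("//regulation/positive")
  tree <- build_category_tree(parts$categories[[1]])
  off <- part_to_statements(parts[1, ], tree, materialize = FALSE)
  on <- part_to_statements(parts[1, ], tree, materialize = TRUE)
  expect_true(all(do.call(paste, off) %in% do.call(paste, on)))
  extra <- setdiff(on$object[on$predicate == "rdf:type"],
                   off$object[off$predicate == "rdf:type"])
  expect_equal(extra, "pr:regulation")
})

test_that("unknown categories error in strict mode, warn and proceed in lenient", {
  parts <- generate_fixture(fixture_config(n_parts = 1, seed = 2))$parts
  parts$categories <- list("//nonexistent/thing")
  tree <- build_category_tree(list("//promoter"))
  expect_error(part_to_statements(parts[1, ], tree, strict = TRUE),
               "//nonexistent/thing")
  expect_warning(st <- part_to_statements(parts[1, ], tree, strict = FALSE),
                 "//nonexistent/thing")
  expect_true("pr:thing_nonexistent" %in% st$object)
})

test_that("missing sequences omit the dnaSequence property entirely", {
  parts <- generate_fixture(fixture_config(n_parts = 2, seed = 3))$parts
  parts$dna_sequence[1] <- ""
  tree <- build_category_tree(unlist(parts$categories))
  st1 <- part_to_statements(parts[1, ], tree)
  st2 <- part_to_statements(parts[2, ], tree)
  expect_false("sbolcore:dnaSequence" %in% st1$predicate)
  expect_true("sbolcore:dnaSequence" %in% st2$predicate)
})

test_that("features map to annotation/feature chains with position literals", {
  fx <- inpaper_fixture(0, seed = 1)
  feat <- fx$features[fx$features$label == "OR1 lambda" &
                        fx$features$part_registry_id == 12036, ]
  st <- feature_to_statements(feat, "sbolcore:rPART12036", part_seq_len = 500)
  ann <- st$object[st$predicate == "sbolcore:annotation"]
  expect_length(ann, 1)
  expect_true(all(c("sbolcore:start", "sbolcore:end", "sbolcore:direction",
                    "sbolcore:feature") %in% st$predicate[st$subject == ann]))
  feat_node <- st$object[st$predicate == "sbolcore:feature"]
  expect_equal(st$object[st$subject == feat_node &
                           st$predicate == "sbolcore:label"], "OR1 lambda")
  expect_true("pr:operator" %in% st$object[st$subject == feat_node])
})

test_that("a feature spanning the whole sequence is fine; overshoot warns but emits", {
  feat <- tibble::tibble(feature_id = 1L, part_registry_id = 1L, label = "x",
                         feature_type = "operator", start = 1L, end = 50L,
                         direction = "forward")
  expect_no_warning(feature_to_statements(feat, "sbolcore:rP1", part_seq_len = 50))
  expect_warning(st <- feature_to_statements(feat, "sbolcore:rP1", part_seq_len = 40),
                 "beyond the part sequence length")
  expect_true("sbolcore:SequenceAnnotation" %in% st$object)
})

test_that("k features on one part yield k annotation and k feature individuals", {
  fx <- inpaper_fixture(0, seed = 1)
  g <- build_knowledgebase(fx$parts, fx$features)
  st <- g$statements
  part <- st$subject[st$predicate == "sbolcore:name" & st$object == "BBa_I12036"]
  anns <- st$object[st$subject == part & st$predicate == "sbolcore:annotation"]
  expect_length(anns, 4)
  feats <- st$object[st$subject %in% anns & st$predicate == "sbolcore:feature"]
  expect_length(unique(feats), 4)
})

test_that("graph building is additive, deduplicating, and part-count faithful", {
  fx <- generate_fixture(fixture_config(n_parts = 60, seed = 21))
  tree <- build_category_tree(unlist(fx$parts$categories))
  g <- build_knowledgebase(fx$parts, fx$features, tree)
  st <- g$statements
  expect_false(any(duplicated(do.call(paste, st))))

  # sum of per-record emissions (plus class axioms) equals the graph
  per_part <- lapply(seq_len(nrow(fx$parts)), function(i) {
    part_to_statements(fx$parts[i, ], tree)
  })
  subjects <- vapply(per_part, function(s) s$subject[1], character(1))
  per_feat <- lapply(seq_len(nrow(fx$features)), function(i) {
    pid <- fx$features$part_registry_id[i]
    feature_to_statements(fx$features[i, ],
                          subjects[match(pid, fx$parts$registry_id)])
  })
  manual <- dplyr::bind_rows(c(
    list(class_axioms_to_statements(emit_class_axioms(tree))),
    per_part, per_feat))
  expect_true(statements_equal(g, manual))

  n_part_subjects <- sum(st$predicate == "rdf:type" & st$object == "sbolcore:Part")
  expect_equal(n_part_subjects, nrow(fx$parts))
})

test_that("empty inputs give a graph of class axioms only", {
  fx <- generate_fixture(fixture_config(n_parts = 0, seed = 1))
  tree <- build_category_tree(list("//promoter"))
  g <- build_knowledgebase(fx$parts, fx$features, tree)
  expect_true(all(g$statements$predicate %in% c("rdf:type", "rdfs:subClassOf")))
  expect_true("pr:promoter" %in% g$statements$subject)
})

test_that("every literal-bearing subject in a built graph carries a type", {
  fx <- generate_fixture(fixture_config(n_parts = 30, seed = 8))
  g <- build_knowledgebase(fx$parts, fx$features)
  st <- g$statements
  lit_subjects <- unique(st$subject[st$object_type != "uri"])
  typed <- unique(st$subject[st$predicate == "rdf:type"])
  expect_true(all(lit_subjects %in% typed))
})
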