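# Brute-force oracles over fixture manifests: plain filters on the record
# tables, written without touching the RDF graph or the SPARQL engine, so
# they can independently confirm every named query.

oracle_part_classes <- function(categories, materialize = TRUE) {
  if (length(categories) == 0) return(character(0))
  cats <- categories
  if (materialize) {
    cats <- c(cats, unlist(lapply(categories, category_ancestors)))
  }
  unique(vapply(unique(cats), class_name_for, character(1), USE.NAMES = FALSE))
}

oracle_members <- function(manifest, class_name, materialize = TRUE) {
  keep <- vapply(manifest$categories, function(cc) {
    class_name %in% oracle_part_classes(cc, materialize)
  }, logical(1))
  sort(manifest$name[keep])
}

oracle_clean <- function(manifest, class_name = NULL) {
  keep <- manifest$has_sequence & manifest$status != "Deleted"
  if (!is.null(class_name)) {
    keep <- keep & manifest$name %in% oracle_members(manifest, class_name)
  }
  sort(manifest$name[keep])
}

oracle_by_status <- function(manifest, statuses) {
  sort(manifest$name[manifest$status %in% statuses])
}

oracle_conjunction <- function(manifest, class_names) {
  sort(Reduce(intersect, lapply(class_names, oracle_members, manifest = manifest)))
}

oracle_dual_with_features <- function(manifest) {
  dual <- oracle_conjunction(manifest, c("promoter", "positive_regulation",
                                         "negative_regulation"))
  with_feat <- manifest$name[lengths(manifest$feature_labels) > 0]
  sort(intersect(dual, with_feat))
}

# Map a query result's part subjects back to registry part names via the
# graph's name literals.
result_part_names <- function(graph, result) {
  st <- graph$statements
  names_by_subject <- stats::setNames(
    st$object[st$predicate == "sbolcore:name"],
    st$subject[st$predicate == "sbolcore:name"])
  sort(unname(names_by_subject[unique(result$rows$part)]))
}

# Run the CLI dispatcher with stdout/stderr swallowed; return the exit status.
capture_cli <- function(args) {
  status <- 1L
  utils::capture.output({
    utils::capture.output({ status <- sbpkb_main(args) }, type = "message")
  }, type = "output")
  status
}

inpaper_graph <- function(n_distractors = 0, seed = 1) {
  fx <- inpaper_fixture(n_distractors, seed = seed)
  list(fx = fx, graph = build_knowledgebase(fx$parts, fx$features))
}
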