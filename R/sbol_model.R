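#' Namespace prefix map used throughout the knowledgebase
#'
#' `sbolcore` holds the core model (Part, SequenceAnnotation, SequenceFeature,
#' the literal properties); `pr` holds the classes auto-generated from the
#' Registry category vocabulary, kept separate to attribute them to their
#' source.
#'
#' @return Named character vector prefix -> IRI.
#' @export
sbpkb_namespaces <- function() {
  c(sbolcore = "http://sbols.org/sbol.owl#",
    pr = "http://partsregistry.org/cat#",
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl = "http://www.w3.org/2002/07/owl#",
    xsd = "http://www.w3.org/2001/XMLSchema#")
}

ID_SCHEME_VERSION <- "1"

base62 <- function(n) {
  alphabet <- c(0:9, LETTERS, letters)
  if (n == 0) return("0")
  out <- character(0)
  while (n > 0) {
    out <- c(alphabet[(n %% 62) + 1], out)
    n <- n %/% 62
  }
  paste(out, collapse = "")
}

#' Mint a deterministic resource identifier
#'
#' Local names are digest-based so rebuilding the knowledgebase from the same
#' input yields identical identifiers (stable diffs, reproducible builds):
#' `"r"` + base62 of a truncated SHA-1 of `kind|registry_id|name` + the
#' registry id digits. Distinct inputs mapping to the same id is practically
#' unreachable but guarded at graph-build time.
#'
#' @param kind One of `"part"`, `"annotation"`, `"feature"`.
#' @param registry_id Integer id of the underlying record.
#' @param name Non-empty string participating in the digest.
#' @return Local name string matching `[A-Za-z][A-Za-z0-9]+`.
#' @export
mint_id <- function(kind = c("part", "annotation", "feature"), registry_id, name) {
  kind <- match.arg(kind)
  stopifnot(length(name) == 1, nzchar(name), length(registry_id) == 1)
  key <- paste(ID_SCHEME_VERSION, kind, registry_id, name, sep = "|")
  hex <- substr(digest::digest(key, algo = "sha1", serialize = FALSE), 1, 10)
  n <- Reduce(function(a, d) a * 16 + d, strtoi(strsplit(hex, "")[[1]], 16L), 0)
  paste0("r", base62(n), registry_id)
}

new_statements <- function(subject = character(0), predicate = character(0),
                           object = character(0), object_type = character(0)) {
  vals <- list(subject = as.character(subject), predicate = as.character(predicate),
               object = as.character(object), object_type = as.character(object_type))
  L <- lengths(vals)
  n <- if (all(L == 1L)) 1L else max(L[L != 1L])
  tibble::new_tibble(lapply(vals, rep_len, n), nrow = n)
}

stmt_uri <- function(subject, predicate, object) {
  new_statements(subject, predicate, object, "uri")
}

stmt_lit <- function(subject, predicate, value, type = "string") {
  new_statements(subject, predicate, as.character(value), type)
}

# literal emission: empty strings are omitted so every query tests presence
lit_if <- function(subject, predicate, value, type = "string") {
  if (length(value) == 1 && (is.na(value) || !nzchar(as.character(value)))) {
    return(new_statements())
  }
  stmt_lit(subject, predicate, value, type)
}

canonical_statements <- function(st) {
  st <- dplyr::distinct(st)
  st[order(st$subject, st$predicate, st$object_type, st$object), ]
}

#' Statements declaring the core classes and the generated category classes
#'
#' Emits `owl:Class` declarations and `rdfs:subClassOf` axioms for each class
#' definition produced by [emit_class_axioms()], plus the core anchor classes.
#'
#' @param classdefs Tibble from [emit_class_axioms()].
#' @return Statement tibble.
#' @export
class_axioms_to_statements <- function(classdefs) {
  core <- c("Part", "SequenceAnnotation", "SequenceFeature", "RegistryCategory")
  st <- stmt_uri(paste0("sbolcore:", core), "rdf:type", "owl:Class")
  if (nrow(classdefs) > 0) {
    iri <- paste0(classdefs$namespace, ":", classdefs$local_name)
    parent <- paste0(classdefs$parent_namespace, ":", classdefs$parent_local_name)
    st <- dplyr::bind_rows(
      st,
      stmt_uri(iri, "rdf:type", "owl:Class"),
      stmt_uri(iri, "rdfs:subClassOf", parent)
    )
  }
  st
}

part_class_memberships <- function(categories, tree, materialize, strict, name) {
  known <- tree$nodes$path
  cats <- vapply(categories, function(c) as_category(c)$raw, character(1))
  missing <- setdiff(cats, known)
  if (length(missing) > 0) {
    msg <- sprintf("part '%s' uses categories not in the tree: %s",
                   name, paste(missing, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  all_cats <- cats
  if (materialize) {
    all_cats <- c(all_cats, unlist(lapply(cats, category_ancestors)))
  }
  unique(vapply(unique(all_cats), class_name_for, character(1), USE.NAMES = FALSE))
}

#' Transform one part record into statements
#'
#' Every part gets `rdf:type sbolcore:Part`, one `rdf:type` per category
#' class (and, with `materialize = TRUE`, per ancestor category class — this
#' is what makes a plain promoter query also return parts tagged only in
#' promoter subcategories), and the literal properties name, type,
#' shortDescription, longDescription, author, status, id, owner_id, date and
#' dnaSequence. Empty-valued literals are omitted: queries test for presence
#' of a property, not for empty strings.
#'
#' @param record One-row slice of a parts tibble.
#' @param tree The `category_tree` backing the class structure.
#' @param materialize Assert ancestor category classes as explicit types.
#' @param strict Error (rather than warn) on a category absent from the tree.
#' @return Statement tibble.
#' @export
part_to_statements <- function(record, tree, materialize = TRUE, strict = TRUE) {
  stopifnot(nrow(record) == 1)
  subj <- paste0("sbolcore:", mint_id("part", record$registry_id, record$name))
  classes <- part_class_memberships(record$categories[[1]], tree,
                                    materialize, strict, record$name)
  dplyr::bind_rows(
    stmt_uri(subj, "rdf:type", "sbolcore:Part"),
    if (length(classes) > 0) stmt_uri(subj, "rdf:type", paste0("pr:", classes)),
    stmt_lit(subj, "sbolcore:name", record$name),
    lit_if(subj, "sbolcore:type", record$part_type),
    lit_if(subj, "sbolcore:shortDescription", record$short_desc),
    lit_if(subj, "sbolcore:longDescription", record$long_desc),
    lit_if(subj, "sbolcore:author", record$author),
    lit_if(subj, "sbolcore:status", record$status),
    stmt_lit(subj, "sbolcore:id", record$registry_id, "integer"),
    stmt_lit(subj, "sbolcore:owner_id", record$owner_id, "integer"),
    lit_if(subj, "sbolcore:date", record$date),
    lit_if(subj, "sbolcore:dnaSequence", record$dna_sequence)
  )
}

#' Transform one sequence-feature record into statements
#'
#' The part links via `sbolcore:annotation` to a SequenceAnnotation individual
#' carrying start/end/direction; the annotation links via `sbolcore:feature`
#' to a SequenceFeature individual typed by its feature type (as a category
#' class token) and labeled with the feature's label. A feature end beyond
#' the part's sequence length draws a warning but is still emitted — Registry
#' data is imperfect and the cleaning queries, not the loader, are the place
#' to exclude records.
#'
#' @param feature One-row slice of a features tibble.
#' @param part_subject Prefixed subject of the owning part.
#' @param part_seq_len Length of the part's sequence, or `NA` to skip the
#'   bounds check.
#' @return Statement tibble.
#' @export
feature_to_statements <- function(feature, part_subject, part_seq_len = NA) {
  stopifnot(nrow(feature) == 1)
  if (!is.na(part_seq_len) && feature$end > part_seq_len) {
    warning(sprintf("feature %d ('%s') ends at %d, beyond the part sequence length %d",
                    feature$feature_id, feature$label, feature$end, part_seq_len),
            call. = FALSE)
  }
  label <- if (nzchar(feature$label)) feature$label else paste0("feature_", feature$feature_id)
  ann <- paste0("sbolcore:", mint_id("annotation", feature$feature_id, label))
  feat <- paste0("sbolcore:", mint_id("feature", feature$feature_id, label))
  type_token <- tolower(gsub("[^A-Za-z0-9_]+", "_", feature$feature_type))
  dplyr::bind_rows(
    stmt_uri(part_subject, "sbolcore:annotation", ann),
    stmt_uri(ann, "rdf:type", "sbolcore:SequenceAnnotation"),
    stmt_lit(ann, "sbolcore:start", feature$start, "integer"),
    stmt_lit(ann, "sbolcore:end", feature$end, "integer"),
    stmt_lit(ann, "sbolcore:direction", feature$direction),
    stmt_uri(ann, "sbolcore:feature", feat),
    stmt_uri(feat, "rdf:type", "sbolcore:SequenceFeature"),
    if (nzchar(type_token)) stmt_uri(feat, "rdf:type", paste0("pr:", type_token)),
    stmt_lit(feat, "sbolcore:label", label)
  )
}

#' Build the Standard Biological Parts knowledge graph
#'
#' Union of the class axioms, all part statements and all feature statements,
#' deduplicated and canonically ordered (so serialization is byte-stable).
#'
#' @param parts,features Tibbles from the readers (or fixture generators).
#' @param tree `category_tree`; defaults to the tree spanned by the parts'
#'   own categories.
#' @param materialize,strict Passed to [part_to_statements()].
#' @param provenance Free-text provenance note stored on the graph.
#' @return A `sbpkb_graph`: list with `statements`, `namespaces`,
#'   `provenance`.
#' @export
build_knowledgebase <- function(parts, features = NULL, tree = NULL,
                                materialize = TRUE, strict = TRUE,
                                provenance = "in-memory records") {
  if (is.null(tree)) tree <- build_category_tree(unlist(parts$categories))
  classdefs <- emit_class_axioms(tree)
  st <- class_axioms_to_statements(classdefs)

  part_subjects <- character(0)
  if (nrow(parts) > 0) {
    subjects <- paste0("sbolcore:",
                       mapply(mint_id, registry_id = parts$registry_id,
                              name = parts$name,
                              MoreArgs = list(kind = "part")))
    if (anyDuplicated(subjects)) {
      stop("minted identifier collision between distinct part records", call. = FALSE)
    }
    part_subjects <- stats::setNames(subjects, as.character(parts$registry_id))
    part_stmts <- lapply(seq_len(nrow(parts)), function(i) {
      part_to_statements(parts[i, ], tree, materialize, strict)
    })
    st <- dplyr::bind_rows(st, part_stmts)
  }

  if (!is.null(features) && nrow(features) > 0) {
    orphans <- !as.character(features$part_registry_id) %in% names(part_subjects)
    if (any(orphans)) {
      msg <- sprintf("%d feature(s) reference parts absent from the parts table (e.g. feature %d)",
                     sum(orphans), features$feature_id[which(orphans)[1]])
      if (strict) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      features <- features[!orphans, ]
    }
    seq_len_by_id <- stats::setNames(nchar(parts$dna_sequence),
                                     as.character(parts$registry_id))
    feat_stmts <- lapply(seq_len(nrow(features)), function(i) {
      pid <- as.character(features$part_registry_id[i])
      slen <- seq_len_by_id[[pid]]
      feature_to_statements(features[i, ], part_subjects[[pid]],
                            if (slen > 0) slen else NA)
    })
    st <- dplyr::bind_rows(st, feat_stmts)
  }

  structure(list(statements = canonical_statements(st),
                 namespaces = sbpkb_namespaces(),
                 provenance = c(provenance, paste0("id scheme v", ID_SCHEME_VERSION))),
            class = "sbpkb_graph")
}

#' @export
print.sbpkb_graph <- function(x, ...) {
  n_parts <- sum(x$statements$predicate == "rdf:type" &
                   x$statements$object == "sbolcore:Part")
  cat(sprintf("SBPkb knowledge graph: %d statements, %d parts\n",
              nrow(x$statements), n_parts))
  cat(sprintf("  provenance: %s\n", paste(x$provenance, collapse = "; ")))
  invisible(x)
}

#' Set equality of two statement tables
#'
#' @param a,b Statement tibbles or `sbpkb_graph`s.
#' @return TRUE if the statement sets coincide.
#' @export
statements_equal <- function(a, b) {
  get_st <- function(x) if (inherits(x, "sbpkb_graph")) x$statements else x
  a <- canonical_statements(get_st(a))
  b <- canonical_statements(get_st(b))
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b), check.attributes = FALSE))
}
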