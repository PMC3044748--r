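#' Parse a Registry category path
#'
#' Category paths are hierarchical tags of the form `//rnap/prokaryote/ecoli/sigma70`.
#' Segments are lower-cased; each must match `[a-z0-9_]+` after normalization.
#'
#' @param raw A single category-path string.
#' @return A `category_path` list with `raw` (normalized) and `segments`.
#' @export
parse_category <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || !nzchar(raw)) {
    stop("category path must be a single non-empty string", call. = FALSE)
  }
  if (!startsWith(raw, "//")) {
    stop(sprintf("category path '%s' must begin with '//'", raw), call. = FALSE)
  }
  body <- substring(raw, 3)
  segments <- tolower(strsplit(body, "/", fixed = TRUE)[[1]])
  if (length(segments) == 0 || any(!nzchar(segments))) {
    stop(sprintf("category path '%s' contains an empty segment", raw), call. = FALSE)
  }
  bad <- !grepl("^[a-z0-9_]+$", segments)
  if (any(bad)) {
    stop(sprintf("category path '%s' has an invalid segment '%s' (allowed: [a-z0-9_]+)",
                 raw, segments[which(bad)[1]]), call. = FALSE)
  }
  structure(list(raw = paste0("//", paste(segments, collapse = "/")),
                 segments = segments),
            class = "category_path")
}

as_category <- function(x) {
  if (inherits(x, "category_path")) x else parse_category(x)
}

#' Proper ancestors of a category path, nearest first
#'
#' Superclass closure over these prefixes is what lets a plain promoter query
#' also retrieve parts tagged only in promoter subcategories.
#'
#' @param path A `category_path` or raw path string.
#' @return Character vector of ancestor paths (nearest first); empty for roots.
#' @export
category_ancestors <- function(path) {
  segs <- as_category(path)$segments
  if (length(segs) <= 1) return(character(0))
  vapply(rev(seq_len(length(segs) - 1)), function(k) {
    paste0("//", paste(segs[seq_len(k)], collapse = "/"))
  }, character(1))
}

#' Build the category tree with ancestor closure
#'
#' Any ancestor missing from the input list is auto-inserted, so the result is
#' always a forest whose root count equals the number of distinct first
#' segments.
#'
#' @param paths List/vector of category paths (strings or `category_path`).
#' @return A `category_tree`: tibble `nodes` with `path`, `parent` (NA for
#'   roots), `depth`, plus `roots`.
#' @export
build_category_tree <- function(paths) {
  parsed <- lapply(paths, as_category)
  all_paths <- unique(unlist(c(
    lapply(parsed, `[[`, "raw"),
    lapply(parsed, category_ancestors)
  )))
  if (is.null(all_paths)) all_paths <- character(0)
  all_paths <- sort(all_paths)
  segs <- strsplit(substring(all_paths, 3), "/", fixed = TRUE)
  depth <- lengths(segs)
  parent <- ifelse(depth > 1,
                   vapply(segs, function(s) {
                     if (length(s) <= 1) NA_character_
                     else paste0("//", paste(s[-length(s)], collapse = "/"))
                   }, character(1)),
                   NA_character_)
  nodes <- tibble::tibble(path = all_paths, parent = parent, depth = depth)
  structure(list(nodes = nodes, roots = all_paths[depth == 1]),
            class = "category_tree")
}

#' @export
print.category_tree <- function(x, ...) {
  cat(sprintf("Category tree: %d nodes under %d top-level categories\n",
              nrow(x$nodes), length(x$roots)))
  invisible(x)
}

#' Class name generated for a category path
#'
#' The generated OWL class for a category is named by the path's segments in
#' reverse order joined by underscores, e.g. `//rnap/prokaryote/ecoli/sigma70`
#' becomes `sigma70_ecoli_prokaryote_rnap`.
#'
#' @param path A `category_path` or raw path string.
#' @return The class local name.
#' @export
class_name_for <- function(path) {
  paste(rev(as_category(path)$segments), collapse = "_")
}

#' Auto-generate the class structure mirroring the category tree
#'
#' One class per tree node, in the partsregistry namespace. Non-roots subclass
#' their category parent's class; roots subclass a neutral core anchor class
#' (`RegistryCategory`) so the generated hierarchy stays connected to the core
#' model without asserting is-a semantics between unrelated vocabularies.
#' Because segment underscores are preserved, two distinct paths can reverse
#' to the same name (e.g. `//a_b` vs `//b/a`); this is detected and raised.
#'
#' @param tree A `category_tree`.
#' @return Tibble of class definitions: `local_name`, `namespace`,
#'   `parent_local_name`, `parent_namespace`, `path`.
#' @export
emit_class_axioms <- function(tree) {
  stopifnot(inherits(tree, "category_tree"))
  nodes <- tree$nodes
  if (nrow(nodes) == 0) {
    return(tibble::tibble(local_name = character(0), namespace = character(0),
                          parent_local_name = character(0),
                          parent_namespace = character(0), path = character(0)))
  }
  local_name <- vapply(nodes$path, class_name_for, character(1), USE.NAMES = FALSE)
  dup <- local_name[duplicated(local_name)]
  if (length(dup) > 0) {
    clash <- nodes$path[local_name == dup[1]]
    stop(sprintf("class name collision: paths %s all generate class '%s'",
                 paste(sprintf("'%s'", clash), collapse = " and "), dup[1]),
         call. = FALSE)
  }
  is_root <- is.na(nodes$parent)
  tibble::tibble(
    local_name = local_name,
    namespace = "pr",
    parent_local_name = ifelse(is_root, "RegistryCategory",
                               vapply(nodes$parent, function(p) {
                                 if (is.na(p)) "RegistryCategory" else class_name_for(p)
                               }, character(1), USE.NAMES = FALSE)),
    parent_namespace = ifelse(is_root, "sbolcore", "pr"),
    path = nodes$path
  )
}

#' Read a category vocabulary file (one path per line)
#'
#' Blank lines and `#` comment lines are ignored.
#'
#' @param path File path.
#' @return Character vector of category paths.
#' @export
read_category_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
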