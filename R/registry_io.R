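#' Table dialect for Registry-style exports
#'
#' The Registry's relational dumps are distributed here as delimited text:
#' UTF-8, tab-separated, first row a header, the multi-valued category cell
#' joined by single spaces, and an empty string where a part has no sequence.
#' `format = "xml"` selects the alternative reader for the original dump
#' shape (one record element per row).
#'
#' @param sep Field separator (fields must not contain it).
#' @param categories_sep Separator inside the category cell.
#' @param format `"tsv"` (default) or `"xml"`.
#' @return A `registry_dialect` list.
#' @export
registry_dialect <- function(sep = "\t", categories_sep = " ", format = c("tsv", "xml")) {
  format <- match.arg(format)
  structure(list(sep = sep, categories_sep = categories_sep, format = format),
            class = "registry_dialect")
}

#' @rdname registry_dialect
#' @export
parts_columns <- function() {
  c("id", "name", "type", "short_desc", "long_desc", "author",
    "owner_id", "status", "date", "categories", "sequence")
}

#' @rdname registry_dialect
#' @export
features_columns <- function() {
  c("id", "part_id", "label", "feature_type", "start", "end", "direction")
}

#' Normalized part status vocabulary
#'
#' Registry statuses are normalized case-insensitively onto
#' {Available, Sent, Deleted, Planning, Unavailable}; anything else maps to
#' "Other" while the raw token is preserved alongside.
#'
#' @param x Character vector of raw status tokens.
#' @return Character vector of normalized tokens.
#' @export
normalize_status <- function(x) {
  canon <- c("Available", "Sent", "Deleted", "Planning", "Unavailable")
  idx <- match(tolower(x), tolower(canon))
  out <- ifelse(is.na(idx), "Other", canon[idx])
  out[is.na(x)] <- "Other"
  out
}

# Strict line splitter: every data line must yield exactly n_cols fields.
split_table_lines <- function(lines, sep, n_cols, path) {
  fields <- strsplit(lines, sep, fixed = TRUE)
  # strsplit drops trailing empties; pad rows that are short only by empties
  n_sep <- lengths(gregexpr(sep, lines, fixed = TRUE))
  n_sep[!grepl(sep, lines, fixed = TRUE)] <- 0L
  counts <- n_sep + 1L
  bad <- which(counts != n_cols)
  if (length(bad) > 0) {
    stop(sprintf("malformed row in '%s': line %d has %d column(s), expected %d",
                 path, bad[1] + 1L, counts[bad[1]], n_cols), call. = FALSE)
  }
  lapply(fields, function(f) c(f, rep("", n_cols - length(f))))
}

read_delimited <- function(path, columns, sep) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop(sprintf("'%s' is empty (header row required)", path), call. = FALSE)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (!identical(header, columns)) {
    stop(sprintf("header of '%s' does not match dialect: got [%s], expected [%s]",
                 path, paste(header, collapse = ", "), paste(columns, collapse = ", ")),
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    rows <- matrix(character(0), nrow = 0, ncol = length(columns))
  } else {
    rows <- do.call(rbind, split_table_lines(body, sep, length(columns), path))
  }
  colnames(rows) <- columns
  tibble::as_tibble(rows, .name_repair = "minimal")
}

parse_int_column <- function(x, what, path) {
  bad <- !grepl("^-?[0-9]+$", x)
  if (any(bad)) {
    stop(sprintf("non-integer %s in '%s': '%s'", what, path, x[which(bad)[1]]),
         call. = FALSE)
  }
  as.integer(x)
}

#' Read a Registry parts table
#'
#' One row per part. The category cell is split into a list of raw category
#' paths, the DNA sequence is lower-cased, and the status token is normalized
#' (the raw token is kept in `status_raw`).
#'
#' @param path Path to the table.
#' @param dialect A [registry_dialect()].
#' @return A tibble with one row per part: `registry_id`, `name`, `part_type`,
#'   `short_desc`, `long_desc`, `author`, `owner_id`, `status`, `status_raw`,
#'   `date`, `categories` (list column of character vectors), `dna_sequence`.
#' @export
read_parts_table <- function(path, dialect = registry_dialect()) {
  if (dialect$format == "xml") {
    raw <- read_records_xml(path, parts_columns())
  } else {
    raw <- read_delimited(path, parts_columns(), dialect$sep)
  }
  seq <- tolower(raw$sequence)
  bad_seq <- nzchar(seq) & grepl("[^acgt]", seq)
  if (any(bad_seq)) {
    stop(sprintf("part '%s' has a sequence with characters outside {a,c,g,t}",
                 raw$name[which(bad_seq)[1]]), call. = FALSE)
  }
  ids <- parse_int_column(raw$id, "registry id", path)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate registry_id in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(raw$name))) {
    stop(sprintf("row with registry_id %d has an empty name",
                 ids[which(!nzchar(raw$name))[1]]), call. = FALSE)
  }
  cats <- lapply(strsplit(raw$categories, dialect$categories_sep, fixed = TRUE),
                 function(x) x[nzchar(x)])
  tibble::tibble(
    registry_id = ids,
    name = raw$name,
    part_type = raw$type,
    short_desc = raw$short_desc,
    long_desc = raw$long_desc,
    author = raw$author,
    owner_id = parse_int_column(raw$owner_id, "owner_id", path),
    status = normalize_status(raw$status),
    status_raw = raw$status,
    date = raw$date,
    categories = cats,
    dna_sequence = seq
  )
}

#' Read a Registry sequence-feature table
#'
#' Positions are 1-based inclusive coordinates on the parent part's own
#' sequence.
#'
#' @inheritParams read_parts_table
#' @return A tibble: `feature_id`, `part_registry_id`, `label`,
#'   `feature_type`, `start`, `end`, `direction`.
#' @export
read_features_table <- function(path, dialect = registry_dialect()) {
  if (dialect$format == "xml") {
    raw <- read_records_xml(path, features_columns())
  } else {
    raw <- read_delimited(path, features_columns(), dialect$sep)
  }
  start <- parse_int_column(raw$start, "start position", path)
  end <- parse_int_column(raw$end, "end position", path)
  bad <- start < 1L | start > end
  if (any(bad)) {
    stop(sprintf("feature %s in '%s' violates 1 <= start <= end (start=%d, end=%d)",
                 raw$id[which(bad)[1]], path, start[which(bad)[1]], end[which(bad)[1]]),
         call. = FALSE)
  }
  dir <- tolower(raw$direction)
  bad_dir <- !dir %in% c("forward", "reverse")
  if (any(bad_dir)) {
    stop(sprintf("feature %s has direction '%s'; expected forward or reverse",
                 raw$id[which(bad_dir)[1]], raw$direction[which(bad_dir)[1]]),
         call. = FALSE)
  }
  tibble::tibble(
    feature_id = parse_int_column(raw$id, "feature id", path),
    part_registry_id = parse_int_column(raw$part_id, "part_id", path),
    label = raw$label,
    feature_type = raw$feature_type,
    start = start,
    end = end,
    direction = dir
  )
}

check_no_sep <- function(x, sep, what) {
  if (any(grepl(sep, x, fixed = TRUE) | grepl("\n", x, fixed = TRUE))) {
    stop(sprintf("%s contains the field separator or a newline; not representable in this dialect", what),
         call. = FALSE)
  }
  x
}

#' Write parts / feature tables in the dialect read by the readers
#'
#' @param parts,features Tibbles as returned by the readers (or built by the
#'   fixture generators).
#' @param path Output path.
#' @param dialect A [registry_dialect()] (`format` must be `"tsv"`).
#' @return `path`, invisibly.
#' @export
write_parts_table <- function(parts, path, dialect = registry_dialect()) {
  stopifnot(dialect$format == "tsv")
  cats <- vapply(parts$categories, paste, character(1), collapse = dialect$categories_sep)
  cells <- cbind(
    as.character(parts$registry_id), parts$name, parts$part_type,
    parts$short_desc, parts$long_desc, parts$author,
    as.character(parts$owner_id), parts$status_raw, parts$date,
    cats, parts$dna_sequence
  )
  check_no_sep(cells, dialect$sep, "a part field")
  lines <- c(paste(parts_columns(), collapse = dialect$sep),
             apply(cells, 1, paste, collapse = dialect$sep))
  if (nrow(parts) == 0) lines <- lines[1]
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_parts_table
#' @export
write_features_table <- function(features, path, dialect = registry_dialect()) {
  stopifnot(dialect$format == "tsv")
  cells <- cbind(
    as.character(features$feature_id), as.character(features$part_registry_id),
    features$label, features$feature_type,
    as.character(features$start), as.character(features$end), features$direction
  )
  check_no_sep(cells, dialect$sep, "a feature field")
  lines <- c(paste(features_columns(), collapse = dialect$sep),
             apply(cells, 1, paste, collapse = dialect$sep))
  if (nrow(features) == 0) lines <- lines[1]
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Reader for the original XML dump shape: <records><record><id>..</id>...</record></records>
read_records_xml <- function(path, columns) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  doc <- xml2::read_xml(path)
  recs <- xml2::xml_children(doc)
  rows <- lapply(recs, function(r) {
    vals <- vapply(columns, function(col) {
      node <- xml2::xml_find_first(r, col)
      if (inherits(node, "xml_missing")) "" else xml2::xml_text(node)
    }, character(1))
    vals
  })
  if (length(rows) == 0) {
    rows <- matrix(character(0), nrow = 0, ncol = length(columns))
  } else {
    rows <- do.call(rbind, rows)
  }
  colnames(rows) <- columns
  tibble::as_tibble(rows, .name_repair = "minimal")
}

#' Validate parts and features jointly
#'
#' Reporting only; inputs are never mutated. Surfaces the defects the
#' downstream cleaning queries are designed to filter: orphan features
#' (foreign key resolves to no part), parts lacking sequences, duplicate
#' registry ids, and statuses outside the normalized vocabulary.
#'
#' @param parts,features Tibbles from the readers.
#' @return A `sbpkb_validation` list: `orphan_features`,
#'   `missing_sequence_ids`, `duplicate_ids`, `nonstandard_status` (tibble of
#'   registry_id, raw status).
#' @export
validate_records <- function(parts, features) {
  nonstd <- parts[parts$status == "Other", c("registry_id", "status_raw")]
  structure(list(
    orphan_features = features$feature_id[
      !features$part_registry_id %in% parts$registry_id],
    missing_sequence_ids = parts$registry_id[!nzchar(parts$dna_sequence)],
    duplicate_ids = unique(parts$registry_id[duplicated(parts$registry_id)]),
    nonstandard_status = nonstd
  ), class = "sbpkb_validation")
}

#' @export
print.sbpkb_validation <- function(x, ...) {
  cat("Registry record validation\n")
  cat(sprintf("  orphan features:     %d\n", length(x$orphan_features)))
  cat(sprintf("  missing sequences:   %d\n", length(x$missing_sequence_ids)))
  cat(sprintf("  duplicate ids:       %d\n", length(x$duplicate_ids)))
  cat(sprintf("  nonstandard status:  %d\n", nrow(x$nonstandard_status)))
  invisible(x)
}

#' @rdname validate_records
#' @export
validation_clean <- function(x) {
  length(x$orphan_features) == 0 && length(x$duplicate_ids) == 0 &&
    nrow(x$nonstandard_status) == 0
}
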