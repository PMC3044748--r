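with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_sequence <- function(len) {
  paste(sample(c("a", "c", "g", "t"), len, replace = TRUE), collapse = "")
}

#' Default per-category assignment probabilities for the generator
#'
#' Leaf paths drawn independently per part; the vocabulary reuses the
#' category paths appearing in the worked promoter examples plus common
#' Registry top-level categories, so generated data exercises realistic
#' structure (including promoters visible only through a subcategory).
#'
#' @return Named numeric vector path -> probability.
#' @export
default_category_weights <- function() {
  c("//promoter" = 0.22,
    "//promoter/constitutive" = 0.05,
    "//regulation/positive" = 0.25,
    "//regulation/negative" = 0.25,
    "//rnap/prokaryote/ecoli/sigma70" = 0.20,
    "//chassis/prokaryote/ecoli" = 0.25,
    "//direction/forward" = 0.40,
    "//terminator" = 0.12,
    "//rbs" = 0.12,
    "//dna" = 0.10,
    "//plasmid" = 0.08,
    "//primer" = 0.05,
    "//classic" = 0.05)
}

feature_label_pool <- function() {
  c("OR1 lambda", "OR2 lambda", "OR1 434", "OR2 434", "TetR",
    "CI lambda O1", "LuxR/HSL", "cI (OR1)", "lacO", "araO2", "T7 term")
}

#' Configuration for the synthetic Registry fixture generator
#'
#' Defaults emulate the Registry snapshot the knowledgebase was designed for:
#' the status mix puts ~38% of parts in Available or Sent and ~4% Deleted,
#' and ~6% of parts lack a sequence, mirroring the snapshot proportions
#' (5,166 of 13,444 Available/Sent; 12,152 of 13,444 with a sequence and not
#' deleted). Categories are drawn independently per part from
#' `category_weights` (leaf paths only — ancestors enter downstream through
#' materialization); a part drawing none receives the highest-weight path so
#' every part is categorized.
#'
#' @param n_parts Number of parts.
#' @param seed RNG seed; the same config is guaranteed byte-identical output.
#' @param category_weights Named probability per category path.
#' @param status_distribution Named probabilities over normalized statuses;
#'   must sum to 1 (tolerance 1e-9).
#' @param p_missing_sequence Probability a part has no sequence.
#' @param mean_features_per_part Poisson mean for features on sequenced parts.
#' @param sequence_length_range Min/max sequence length (nt).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_parts = 500, seed = 1,
                           category_weights = default_category_weights(),
                           status_distribution = c(Available = 0.30, Sent = 0.08,
                                                   Planning = 0.40, Unavailable = 0.18,
                                                   Deleted = 0.04),
                           p_missing_sequence = 0.06,
                           mean_features_per_part = 0.6,
                           sequence_length_range = c(40L, 400L)) {
  stopifnot(n_parts >= 0, length(sequence_length_range) == 2,
            all(category_weights >= 0 & category_weights <= 1),
            p_missing_sequence >= 0, p_missing_sequence <= 1,
            mean_features_per_part >= 0)
  if (abs(sum(status_distribution) - 1) > 1e-9) {
    stop("status_distribution must sum to 1", call. = FALSE)
  }
  if (mean_features_per_part > 0 &&
      (p_missing_sequence >= 1 || sequence_length_range[2] < 20)) {
    stop("infeasible config: features requested but sequences are absent or too short",
         call. = FALSE)
  }
  structure(list(n_parts = as.integer(n_parts), seed = as.integer(seed),
                 category_weights = category_weights,
                 status_distribution = status_distribution,
                 p_missing_sequence = p_missing_sequence,
                 mean_features_per_part = mean_features_per_part,
                 sequence_length_range = as.integer(sequence_length_range)),
            class = "fixture_config")
}

author_pool <- function() {
  c("A. Turing", "R. Franklin", "B. McClintock", "S. Brenner", "E. Charpentier",
    "F. Jacob", "J. Monod", "L. Pauling")
}

#' Generate a synthetic Registry fixture
#'
#' Seeded and reproducible: the same config yields byte-identical table files.
#' Returns the in-memory tables together with a manifest of the ground truth
#' (categories, status, sequence presence, feature labels per part) that
#' oracle code can filter directly, without touching the RDF layer.
#'
#' @param config A [fixture_config()].
#' @param dir If non-NULL, directory where `parts.tsv`, `features.tsv` and
#'   `manifest.json` are written.
#' @return List: `parts`, `features`, `manifest`, and `paths` when written.
#' @export
generate_fixture <- function(config = fixture_config(), dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  out <- with_seed(config$seed, {
    n <- config$n_parts
    if (n == 0) {
      parts <- empty_parts()
      features <- empty_features()
    } else {
      ids <- 1000L + seq_len(n)
      cw <- config$category_weights
      cats <- lapply(seq_len(n), function(i) {
        drawn <- names(cw)[stats::runif(length(cw)) < cw]
        if (length(drawn) == 0) drawn <- names(cw)[which.max(cw)]
        drawn
      })
      status <- sample(names(config$status_distribution), n, replace = TRUE,
                       prob = config$status_distribution)
      has_seq <- stats::runif(n) >= config$p_missing_sequence
      lens <- sample(seq(config$sequence_length_range[1],
                         config$sequence_length_range[2]), n, replace = TRUE)
      seqs <- ifelse(has_seq,
                     vapply(lens, random_sequence, character(1)), "")
      parts <- tibble::tibble(
        registry_id = ids,
        name = sprintf("BBa_S%05d", ids),
        part_type = ifelse(vapply(cats, function(cc) "//promoter" %in% cc ||
                                    "//promoter/constitutive" %in% cc, logical(1)),
                           "Regulatory", "Other"),
        short_desc = sprintf("synthetic part %d", ids),
        long_desc = sprintf("Synthetic fixture part %d for pipeline testing.", ids),
        author = sample(author_pool(), n, replace = TRUE),
        owner_id = sample(1000:9999, n, replace = TRUE),
        status = status,
        status_raw = status,
        date = sprintf("%d/%d/%d", sample(1:12, n, TRUE), sample(1:28, n, TRUE),
                       sample(2004:2010, n, TRUE)),
        categories = cats,
        dna_sequence = seqs
      )
      n_feat <- ifelse(has_seq, stats::rpois(n, config$mean_features_per_part), 0L)
      feat_rows <- list()
      fid <- 1L
      for (i in seq_len(n)) {
        if (n_feat[i] == 0) next
        L <- nchar(seqs[i])
        for (k in seq_len(n_feat[i])) {
          start <- sample(seq_len(max(1L, L - 12L)), 1)
          end <- min(L, start + sample(4:25, 1))
          feat_rows[[length(feat_rows) + 1]] <- tibble::tibble(
            feature_id = fid,
            part_registry_id = parts$registry_id[i],
            label = sample(feature_label_pool(), 1),
            feature_type = sample(c("operator", "terminator", "promoter", "rbs", "tag"),
                                  1, prob = c(0.4, 0.15, 0.15, 0.15, 0.15)),
            start = start, end = end,
            direction = sample(c("forward", "reverse"), 1))
          fid <- fid + 1L
        }
      }
      features <- if (length(feat_rows) == 0) empty_features() else
        dplyr::bind_rows(feat_rows)
    }
    list(parts = parts, features = features)
  })
  out$manifest <- build_manifest(out$parts, out$features)
  if (!is.null(dir)) out$paths <- write_fixture(out, dir)
  out
}

empty_parts <- function() {
  tibble::tibble(registry_id = integer(0), name = character(0),
                 part_type = character(0), short_desc = character(0),
                 long_desc = character(0), author = character(0),
                 owner_id = integer(0), status = character(0),
                 status_raw = character(0), date = character(0),
                 categories = list(), dna_sequence = character(0))
}

empty_features <- function() {
  tibble::tibble(feature_id = integer(0), part_registry_id = integer(0),
                 label = character(0), feature_type = character(0),
                 start = integer(0), end = integer(0), direction = character(0))
}

build_manifest <- function(parts, features) {
  labels <- split(features$label, features$part_registry_id)
  tibble::tibble(
    registry_id = parts$registry_id,
    name = parts$name,
    categories = parts$categories,
    status = normalize_status(parts$status_raw),
    has_sequence = nzchar(parts$dna_sequence),
    feature_labels = lapply(as.character(parts$registry_id), function(id) {
      lb <- labels[[id]]
      if (is.null(lb)) character(0) else lb
    })
  )
}

write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(parts = file.path(dir, "parts.tsv"),
                features = file.path(dir, "features.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_parts_table(fx$parts, paths$parts)
  write_features_table(fx$features, paths$features)
  # one JSON record per line so oracle code can stream it
  lines <- vapply(seq_len(nrow(fx$manifest)), function(i) {
    row <- fx$manifest[i, ]
    jsonlite::toJSON(list(registry_id = row$registry_id, name = row$name,
                          categories = row$categories[[1]], status = row$status,
                          has_sequence = row$has_sequence,
                          feature_labels = row$feature_labels[[1]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, paths$manifest, useBytes = TRUE)
  paths
}

#' Read a fixture manifest written by [generate_fixture()]
#'
#' @param path Path to `manifest.json` (one JSON record per line).
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    registry_id = vapply(rows, function(r) as.integer(r$registry_id), integer(1)),
    name = vapply(rows, `[[`, character(1), "name"),
    categories = lapply(rows, function(r) as.character(r$categories)),
    status = vapply(rows, `[[`, character(1), "status"),
    has_sequence = vapply(rows, `[[`, logical(1), "has_sequence"),
    feature_labels = lapply(rows, function(r) as.character(r$feature_labels))
  )
}

table1_part <- function() {
  tibble::tibble(
    registry_id = 9598L,
    name = "BBa_I746365",
    part_type = "Regulatory",
    short_desc = "PLL promoter from P4 phage",
    long_desc = paste0(
      "This is the PLL promoter taken from the P4 phage genome. It is an ",
      "inducible promoter that is activated by a class of activators, ",
      "including P2 ogr (I746350), PSP3 pag (I746351) and phiR73 delta ",
      "(I746352). These different activators should cause different levels ",
      "of activity of the PLL promoter."),
    author = "Stefan Milde",
    owner_id = 2122L,
    status = "Available",
    status_raw = "Available",
    date = "9/11/2007",
    categories = list(c("//promoter", "//regulation/positive",
                        "//direction/forward", "//chassis/prokaryote/ecoli",
                        "//rnap/prokaryote/ecoli/sigma70")),
    dna_sequence = paste0(
      "cgctttattttgtgaatattttcagcagacgcaacaggggggatttgttcaggctgtctt",
      "acaatggctgtgtgttttttgttcatctccac")
  )
}

table2_rows <- function() {
  tibble::tribble(
    ~name, ~short_desc, ~author, ~feature_labels,
    "BBa_I12036", "Modified lamdba Prm promoter", "Hans",
    c("OR1 lambda", "OR2 lambda", "OR1 434", "OR2 434"),
    "BBa_I12006", "Modified lamdba Prm promoter", "mcnamara",
    c("OR1 lambda", "OR2 lambda", "OR1 434"),
    "BBa_I12040", "Modified lambda P(RM) promoter", "ryhsiao",
    c("OR1 lambda", "OR2 lambda", "OR1 434", "OR2 434"),
    "BBa_I14015", "P(Las) TetO", "Vijayan, V., Hsu, A., Fomundam, L.",
    c("TetR"),
    "BBa_I14016", "P(Las) CIO", "Vijayan, V., Hsu, A., Fomundam, L.",
    c("CI lambda O1"),
    "BBa_I1051", "Lux cassette right promoter",
    "Mahajan, V.S., Marinescu, V.D., Chow, B., Wissner-Gross, A.D., Carr, P.",
    c("cI (OR1)", "LuxR/HSL")
  )
}

#' The in-paper fixture: the printed describe example plus the six
#' dual-regulated promoters
#'
#' Encodes the single promoter of the printed describe result (BBa_I746365
#' with its full property set, categories, and 92-nt sequence) and the six
#' dual-regulated promoter parts with their printed names, short
#' descriptions, authors and operator-site feature labels. Registry ids for
#' the six parts derive from the digits of their names; their sequences and
#' the feature coordinates are not printed anywhere, so they are synthesized
#' deterministically from `seed` and kept within sequence bounds. Optional
#' distractors are promoter parts that miss at least one of the two
#' regulation categories or carry no features, built from the same category
#' vocabulary, so they can never enter the dual-regulated-with-features
#' result.
#'
#' @param n_distractors Number of distractor promoter parts to add.
#' @param seed Seed for the synthesized sequences/coordinates.
#' @param dir If non-NULL, write tables + manifest there.
#' @return Same shape as [generate_fixture()].
#' @export
inpaper_fixture <- function(n_distractors = 0, seed = 1, dir = NULL) {
  stopifnot(n_distractors >= 0)
  fx <- with_seed(seed, {
    t2 <- table2_rows()
    ids <- as.integer(sub("^BBa_I", "", t2$name))
    seqs <- vapply(sample(80:160, nrow(t2), replace = TRUE),
                   random_sequence, character(1))
    t2_parts <- tibble::tibble(
      registry_id = ids,
      name = t2$name,
      part_type = "Regulatory",
      short_desc = t2$short_desc,
      long_desc = "",
      author = t2$author,
      owner_id = 3000L + seq_len(nrow(t2)),
      status = "Available",
      status_raw = "Available",
      date = "4/6/2010",
      categories = rep(list(c("//promoter", "//regulation/positive",
                              "//regulation/negative")), nrow(t2)),
      dna_sequence = seqs
    )
    feat_rows <- list()
    fid <- 1L
    for (i in seq_len(nrow(t2))) {
      L <- nchar(seqs[i])
      for (lab in t2$feature_labels[[i]]) {
        start <- sample(seq_len(L - 20L), 1)
        feat_rows[[length(feat_rows) + 1]] <- tibble::tibble(
          feature_id = fid, part_registry_id = ids[i], label = lab,
          feature_type = "operator", start = start,
          end = start + sample(8:17, 1), direction = "forward")
        fid <- fid + 1L
      }
    }
    parts <- dplyr::bind_rows(table1_part(), t2_parts)
    if (n_distractors > 0) {
      d_ids <- 90000L + seq_len(n_distractors)
      d_cats <- lapply(seq_len(n_distractors), function(i) {
        # promoter but never both regulation classes
        c("//promoter",
          sample(list(character(0), "//regulation/positive",
                      "//regulation/negative",
                      "//rnap/prokaryote/ecoli/sigma70"), 1)[[1]])
      })
      distractors <- tibble::tibble(
        registry_id = d_ids,
        name = sprintf("BBa_D%05d", d_ids),
        part_type = "Regulatory",
        short_desc = "distractor promoter",
        long_desc = "",
        author = sample(author_pool(), n_distractors, replace = TRUE),
        owner_id = 5000L + seq_len(n_distractors),
        status = "Available",
        status_raw = "Available",
        date = "4/6/2010",
        categories = d_cats,
        dna_sequence = vapply(sample(60:120, n_distractors, replace = TRUE),
                              random_sequence, character(1))
      )
      parts <- dplyr::bind_rows(parts, distractors)
    }
    list(parts = parts,
         features = if (length(feat_rows) == 0) empty_features() else
           dplyr::bind_rows(feat_rows))
  })
  fx$manifest <- build_manifest(fx$parts, fx$features)
  if (!is.null(dir)) fx$paths <- write_fixture(fx, dir)
  fx
}
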