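#' Construct a query specification
#'
#' A query spec pairs a SPARQL template (placeholders written `{{name}}`) with
#' its parameter values and a note on what the query asks. Rendering
#' substitutes parameters textually; class-name parameters are validated
#' against `[a-z0-9_]+` before substitution so rendering always yields
#' syntactically valid SPARQL.
#'
#' @param name Query name token.
#' @param sparql_template Template text.
#' @param params Named list of parameter values.
#' @param note What the query asks, in words.
#' @return A `query_spec`.
#' @export
query_spec <- function(name, sparql_template, params = list(), note = "") {
  structure(list(name = name, sparql_template = sparql_template,
                 params = params, note = note),
            class = "query_spec")
}

#' @rdname query_spec
#' @export
render_query <- function(spec, params = list()) {
  stopifnot(inherits(spec, "query_spec"))
  params <- utils::modifyList(spec$params, params)
  text <- spec$sparql_template
  for (nm in names(params)) {
    text <- gsub(paste0("{{", nm, "}}"), params[[nm]], text, fixed = TRUE)
  }
  if (grepl("\\{\\{[a-zA-Z_]+\\}\\}", text)) {
    stop(sprintf("query '%s' has unfilled placeholders", spec$name), call. = FALSE)
  }
  text
}

#' @export
print.query_spec <- function(x, ...) {
  cat(sprintf("Query '%s': %s\n", x$name, x$note))
  cat(render_query(x), "\n")
  invisible(x)
}

check_class_token <- function(class_name) {
  if (!grepl("^[a-z0-9_]+$", class_name) && class_name != "Part") {
    stop(sprintf("'%s' is not a valid class token", class_name), call. = FALSE)
  }
  class_name
}

graph_class_names <- function(graph) {
  st <- graph$statements
  cls <- st$subject[st$predicate == "rdf:type" & st$object == "owl:Class"]
  sub("^[^:]*:", "", cls)
}

warn_unknown_class <- function(graph, class_names) {
  unknown <- setdiff(class_names, graph_class_names(graph))
  if (length(unknown) > 0) {
    warning(sprintf("class(es) not declared in this knowledgebase: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

class_iri <- function(class_name) {
  if (class_name %in% c("Part", "SequenceAnnotation", "SequenceFeature",
                        "RegistryCategory")) {
    paste0("sbolcore:", class_name)
  } else {
    paste0("pr:", check_class_token(class_name))
  }
}

#' The named query bank
#'
#' The reusable promoter-refinement workflow, each query documented by the
#' design question it answers:
#' \describe{
#'   \item{parts_by_class}{Which parts are annotated with a given category
#'     class (e.g. all promoters)?}
#'   \item{clean_parts}{Of those, which have a DNA sequence listed and have
#'     not been marked for deletion?}
#'   \item{by_status}{Which parts carry one of a set of statuses (e.g.
#'     Available or Sent as physical clones)?}
#'   \item{conjunctive_classes}{Which parts belong to all of several classes
#'     at once (e.g. promoter and sigma70_ecoli_prokaryote_rnap; or the
#'     dual-regulation pair needed for a relaxation oscillator)?}
#'   \item{dual_regulated_features}{Dual-regulated promoters that carry at
#'     least one annotated feature — candidate operator sites — returned with
#'     name, description, author and feature label.}
#' }
#'
#' @return Named list of `query_spec`s.
#' @export
query_bank <- function() {
  list(
    parts_by_class = query_spec(
      "parts_by_class",
      "SELECT DISTINCT ?part WHERE {
         ?part rdf:type sbolcore:Part .
         ?part rdf:type {{class_iri}} .
       }",
      note = "all parts annotated with a category class"),
    clean_parts = query_spec(
      "clean_parts",
      "SELECT DISTINCT ?part WHERE {
         ?part rdf:type sbolcore:Part .
         ?part rdf:type {{class_iri}} .
         ?part sbolcore:dnaSequence ?seq .
         ?part sbolcore:status ?status .
         FILTER ( ?status != \"Deleted\" )
       }",
      note = "class members with a DNA sequence, not marked for deletion"),
    by_status = query_spec(
      "by_status",
      "SELECT DISTINCT ?part WHERE {
         ?part rdf:type sbolcore:Part .
         ?part sbolcore:status ?status .
         FILTER ( ?status IN ( {{status_list}} ) )
       }",
      note = "parts whose status is one of a given set"),
    conjunctive_classes = query_spec(
      "conjunctive_classes",
      "SELECT DISTINCT ?part WHERE {
         ?part rdf:type sbolcore:Part .
{{class_patterns}}
       }",
      note = "parts typed by every class in a list"),
    dual_regulated_features = query_spec(
      "dual_regulated_features",
      "SELECT DISTINCT ?part ?name ?short ?author ?flabel WHERE {
         ?part rdf:type pr:promoter .
         ?part rdf:type pr:positive_regulation .
         ?part rdf:type pr:negative_regulation .
         ?part sbolcore:name ?name .
         ?part sbolcore:shortDescription ?short .
         ?part sbolcore:author ?author .
         ?part sbolcore:annotation ?ann .
         ?ann sbolcore:feature ?feat .
         ?feat sbolcore:label ?flabel .
       }",
      note = "dual-regulated promoters with annotated binding-site features")
  )
}

#' Named queries of the refinement workflow
#'
#' Thin wrappers rendering [query_bank()] templates and executing them with
#' [sparql_select()]. All results are DISTINCT over the part subject, so no
#' part is ever reported twice (the manual Registry-browsing route needs
#' spreadsheet de-duplication; the query layer makes duplicates impossible).
#'
#' @param graph A `sbpkb_graph`.
#' @param class_name A generated class token (e.g. `"promoter"`), or
#'   `"Part"` for all parts.
#' @return A `query_result`.
#' @export
q_parts_by_class <- function(graph, class_name) {
  warn_unknown_class(graph, class_name)
  sparql_select(graph, render_query(query_bank()$parts_by_class,
                                    list(class_iri = class_iri(class_name))),
                subject_var = "part")
}

#' All statements describing the members of a class
#'
#' The describe step of query refinement: lists the complete set of
#' properties attached to every part of a class, so a researcher can discover
#' criteria (status, sequence presence, finer category classes) to narrow
#' the next query with.
#'
#' @inheritParams q_parts_by_class
#' @param mode Describe mode, see [sbpkb_describe()].
#' @return Statement tibble.
#' @export
q_describe_class <- function(graph, class_name, mode = "forward") {
  res <- q_parts_by_class(graph, class_name)
  sbpkb_describe(graph, res$rows$part, mode = mode)
}

#' @rdname q_parts_by_class
#' @export
q_clean_parts <- function(graph, class_name = "Part") {
  warn_unknown_class(graph, class_name)
  sparql_select(graph, render_query(query_bank()$clean_parts,
                                    list(class_iri = class_iri(class_name))),
                subject_var = "part")
}

#' @rdname q_parts_by_class
#' @param statuses Character vector of normalized status tokens.
#' @export
q_by_status <- function(graph, statuses) {
  if (length(statuses) == 0) {
    return(new_query_result("part", tibble::tibble(part = character(0)), "part"))
  }
  status_list <- paste(sprintf('"%s"', normalize_status(statuses)), collapse = ", ")
  sparql_select(graph, render_query(query_bank()$by_status,
                                    list(status_list = status_list)),
                subject_var = "part")
}

#' @rdname q_parts_by_class
#' @param class_names Character vector of class tokens, all required.
#' @export
q_conjunctive_classes <- function(graph, class_names) {
  stopifnot(length(class_names) >= 1)
  warn_unknown_class(graph, class_names)
  patterns <- paste(sprintf("         ?part rdf:type %s .",
                            vapply(class_names, class_iri, character(1))),
                    collapse = "\n")
  sparql_select(graph, render_query(query_bank()$conjunctive_classes,
                                    list(class_patterns = patterns)),
                subject_var = "part")
}

#' @rdname q_parts_by_class
#' @export
q_dual_regulated_with_features <- function(graph) {
  sparql_select(graph, query_bank()$dual_regulated_features,
                subject_var = "part")
}

#' Write a query result as TSV or SPARQL-results JSON
#'
#' @param result A `query_result`.
#' @param path Output path ("" for stdout).
#' @param format `"tsv"` or `"json"` (SPARQL 1.1 results JSON shape).
#' @return `path` invisibly.
#' @export
write_query_result <- function(result, path = "", format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- c(paste(result$variables, collapse = "\t"),
               if (nrow(result$rows) > 0)
                 apply(as.data.frame(result$rows), 1, paste, collapse = "\t"))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    obj <- list(
      head = list(vars = result$variables),
      results = list(bindings = lapply(seq_len(nrow(result$rows)), function(i) {
        row <- result$rows[i, ]
        stats::setNames(lapply(result$variables, function(v) {
          list(type = "literal", value = row[[v]])
        }), result$variables)
      }))
    )
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
    if (identical(path, "")) cat(json, "\n") else writeLines(json, path, useBytes = TRUE)
  }
  invisible(path)
}
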