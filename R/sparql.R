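#' @name sparql
#' @title SPARQL subset engine
#'
#' @description
#' Executes SELECT queries over a `sbpkb_graph` with plain basic-graph-pattern
#' semantics: no entailment beyond the asserted statements (superclass
#' materialization happens at graph-build time, which keeps the query dialect
#' plain). Supported grammar:
#'
#' ```
#' PREFIX pfx: <iri> ...
#' SELECT [DISTINCT] (?var ... | *)
#' WHERE { triple ('.' triple)* (FILTER ( expr ))* }
#' expr  := term (=|!=) term | term [NOT] IN (term, ...)
#'        | !expr | expr && expr | expr || expr | ( expr )
#' term  := ?var | pfx:local | <iri> | "literal" | integer
#' ```
#'
#' Unsupported SPARQL (OPTIONAL, UNION, property paths, ';' lists) raises a
#' syntax error carrying the character position.
NULL

sparql_tokenize <- function(text) {
  patterns <- c(
    ws      = "^\\s+",
    comment = "^#[^\n]*",
    iri     = "^<[^>]*>",
    string  = '^"(?:[^"\\\\]|\\\\.)*"',
    var     = "^[?$][A-Za-z_][A-Za-z0-9_]*",
    pname   = "^[A-Za-z_][A-Za-z0-9_-]*:[A-Za-z_][A-Za-z0-9_.-]*",
    number  = "^-?[0-9]+",
    word    = "^[A-Za-z_][A-Za-z0-9_]*",
    op      = "^(!=|&&|\\|\\||[{}().,=!;*:])"
  )
  tokens <- list()
  pos <- 1
  n <- nchar(text)
  while (pos <= n) {
    rest <- substring(text, pos)
    matched <- FALSE
    for (ty in names(patterns)) {
      m <- regexpr(patterns[[ty]], rest, perl = TRUE)
      if (m != -1) {
        len <- attr(m, "match.length")
        if (!ty %in% c("ws", "comment")) {
          tokens[[length(tokens) + 1]] <- list(type = ty,
                                               value = substr(rest, 1, len),
                                               pos = pos)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("SPARQL syntax error at position %d: unexpected character '%s'",
                   pos, substr(rest, 1, 1)), call. = FALSE)
    }
  }
  tokens
}

# recursive-descent parser over the token stream; state kept in an environment
sparql_parse <- function(text) {
  toks <- sparql_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1
  peek <- function() if (st$i <= length(toks)) toks[[st$i]] else NULL
  advance <- function() { t <- peek(); st$i <- st$i + 1; t }
  fail <- function(expected) {
    t <- peek()
    if (is.null(t)) stop(sprintf("SPARQL syntax error at end of input: expected %s", expected),
                         call. = FALSE)
    stop(sprintf("SPARQL syntax error at position %d: expected %s, found '%s'",
                 t$pos, expected, t$value), call. = FALSE)
  }
  expect_word <- function(w) {
    t <- peek()
    if (is.null(t) || t$type != "word" || toupper(t$value) != w) fail(sprintf("'%s'", w))
    advance()
  }
  expect_op <- function(o) {
    t <- peek()
    if (is.null(t) || t$type != "op" || t$value != o) fail(sprintf("'%s'", o))
    advance()
  }
  at_word <- function(w) {
    t <- peek()
    !is.null(t) && t$type == "word" && toupper(t$value) == w
  }
  at_op <- function(o) {
    t <- peek()
    !is.null(t) && t$type == "op" && t$value == o
  }

  prefixes <- character(0)
  while (at_word("PREFIX")) {
    advance()
    t <- peek()
    if (is.null(t) || t$type != "word") fail("a prefix name")
    pfx <- advance()$value
    expect_op(":")
    t <- peek()
    if (is.null(t) || t$type != "iri") fail("an IRI in angle brackets")
    prefixes[[pfx]] <- sub("^<(.*)>$", "\\1", advance()$value)
  }

  term <- function() {
    t <- peek()
    if (is.null(t)) fail("a term")
    if (t$type == "var") {
      advance(); return(list(kind = "var", value = substring(t$value, 2)))
    }
    if (t$type == "pname") {
      advance(); return(list(kind = "uri", value = t$value))
    }
    if (t$type == "iri") {
      advance(); return(list(kind = "iri", value = sub("^<(.*)>$", "\\1", t$value)))
    }
    if (t$type == "string") {
      advance()
      return(list(kind = "literal",
                  value = unescape_turtle(sub('^"(.*)"$', "\\1", t$value))))
    }
    if (t$type == "number") {
      advance(); return(list(kind = "literal", value = t$value))
    }
    if (t$type == "word" && t$value == "a") {
      advance(); return(list(kind = "uri", value = "rdf:type"))
    }
    fail("a variable, IRI, prefixed name or literal")
  }

  parse_primary <- function() {
    if (at_op("!")) { advance(); return(list(op = "not", x = parse_primary())) }
    if (at_op("(")) {
      advance(); e <- parse_or(); expect_op(")"); return(e)
    }
    lhs <- term()
    t <- peek()
    if (!is.null(t) && t$type == "op" && t$value %in% c("=", "!=")) {
      op <- advance()$value
      return(list(op = if (op == "=") "eq" else "neq", lhs = lhs, rhs = term()))
    }
    if (at_word("NOT")) {
      advance(); expect_word("IN")
      return(list(op = "not_in", lhs = lhs, set = parse_term_list()))
    }
    if (at_word("IN")) {
      advance()
      return(list(op = "in", lhs = lhs, set = parse_term_list()))
    }
    fail("a comparison operator")
  }
  parse_term_list <- function() {
    expect_op("(")
    out <- list()
    if (!at_op(")")) {
      out[[1]] <- term()
      while (at_op(",")) { advance(); out[[length(out) + 1]] <- term() }
    }
    expect_op(")")
    out
  }
  parse_and <- function() {
    e <- parse_primary()
    while (at_op("&&")) { advance(); e <- list(op = "and", lhs = e, rhs = parse_primary()) }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (at_op("||")) { advance(); e <- list(op = "or", lhs = e, rhs = parse_and()) }
    e
  }

  expect_word("SELECT")
  distinct <- FALSE
  if (at_word("DISTINCT")) { advance(); distinct <- TRUE }
  vars <- character(0)
  star <- FALSE
  if (at_op("*")) { advance(); star <- TRUE }
  else {
    while (!is.null(peek()) && peek()$type == "var") {
      vars <- c(vars, substring(advance()$value, 2))
    }
    if (length(vars) == 0) fail("projection variables or '*'")
  }
  if (at_word("WHERE")) advance()
  expect_op("{")
  triples <- list()
  filters <- list()
  repeat {
    if (at_op("}")) { advance(); break }
    if (at_word("FILTER")) {
      advance(); expect_op("(")
      filters[[length(filters) + 1]] <- parse_or()
      expect_op(")")
      if (at_op(".")) advance()
      next
    }
    if (at_word("OPTIONAL") || at_word("UNION") || at_op(";")) {
      fail("a triple pattern or FILTER (OPTIONAL/UNION/';' lists are not supported)")
    }
    s <- term(); p <- term(); o <- term()
    triples[[length(triples) + 1]] <- list(s = s, p = p, o = o)
    if (at_op(".")) advance()
  }
  if (!is.null(peek())) fail("end of query")
  list(prefixes = prefixes, distinct = distinct, star = star,
       vars = vars, triples = triples, filters = filters)
}

resolve_uri_term <- function(term, prefixes, ns) {
  if (term$kind == "iri") return(contract_iri(term$value, ns))
  pfx <- sub(":.*$", "", term$value)
  if (pfx %in% names(prefixes)) {
    full <- paste0(prefixes[[pfx]], sub("^[^:]*:", "", term$value))
    return(contract_iri(full, ns))
  }
  if (pfx %in% names(ns)) return(term$value)
  stop(sprintf("unknown prefix '%s' in query", pfx), call. = FALSE)
}

match_triple <- function(st, tp, prefixes, ns) {
  keep <- rep(TRUE, nrow(st))
  bind_cols <- character(0)
  for (role in c("s", "p", "o")) {
    t <- tp[[role]]
    col <- c(s = "subject", p = "predicate", o = "object")[[role]]
    if (t$kind == "var") {
      bind_cols[t$value] <- col
    } else if (t$kind == "literal") {
      if (role != "o") stop("literals may only appear in object position", call. = FALSE)
      keep <- keep & st$object_type != "uri" & st$object == t$value
    } else {
      v <- resolve_uri_term(t, prefixes, ns)
      if (role == "o") keep <- keep & st$object_type == "uri" & st$object == v
      else keep <- keep & st[[col]] == v
    }
  }
  matched <- st[keep, ]
  out <- tibble::as_tibble(stats::setNames(
    lapply(unname(bind_cols), function(col) matched[[col]]), names(bind_cols)))
  if (length(bind_cols) == 0) out <- tibble::tibble(.matches = nrow(matched) > 0)
  dplyr::distinct(out)
}

eval_filter <- function(expr, bindings, prefixes, ns) {
  val <- function(t) {
    if (t$kind == "var") {
      if (!t$value %in% names(bindings)) {
        stop(sprintf("filter references unbound variable ?%s", t$value), call. = FALSE)
      }
      bindings[[t$value]]
    } else if (t$kind == "literal") rep(t$value, nrow(bindings))
    else rep(resolve_uri_term(t, prefixes, ns), nrow(bindings))
  }
  switch(expr$op,
    eq  = val(expr$lhs) == val(expr$rhs),
    neq = val(expr$lhs) != val(expr$rhs),
    "in" = val(expr$lhs) %in% vapply(expr$set, function(t) {
      if (t$kind == "var") stop("IN list must be constant", call. = FALSE)
      if (t$kind == "literal") t$value else resolve_uri_term(t, prefixes, ns)
    }, character(1)),
    not_in = !eval_filter(list(op = "in", lhs = expr$lhs, set = expr$set),
                          bindings, prefixes, ns),
    not = !eval_filter(expr$x, bindings, prefixes, ns),
    and = eval_filter(expr$lhs, bindings, prefixes, ns) &
          eval_filter(expr$rhs, bindings, prefixes, ns),
    or  = eval_filter(expr$lhs, bindings, prefixes, ns) |
          eval_filter(expr$rhs, bindings, prefixes, ns),
    stop(sprintf("unsupported filter operator '%s'", expr$op), call. = FALSE)
  )
}

#' Execute a SPARQL SELECT query over a knowledge graph
#'
#' @param graph A `sbpkb_graph`.
#' @param query SPARQL text, or a `query_spec` from [query_bank()] /
#'   [query_spec()].
#' @param subject_var Variable whose distinct bindings are counted as
#'   `distinct_subjects` (default: the first projected variable).
#' @return A `query_result`: `variables`, `rows` (tibble of bindings),
#'   `distinct_subjects`.
#' @export
sparql_select <- function(graph, query, subject_var = NULL) {
  if (inherits(query, "query_spec")) query <- render_query(query)
  stopifnot(inherits(graph, "sbpkb_graph"))
  q <- sparql_parse(query)
  st <- graph$statements
  ns <- graph$namespaces

  bindings <- tibble::tibble(.rows = 1)
  for (tp in q$triples) {
    m <- match_triple(st, tp, q$prefixes, ns)
    if (".matches" %in% names(m)) {
      if (!any(m$.matches)) bindings <- bindings[0, , drop = FALSE]
      next
    }
    shared <- intersect(names(bindings), names(m))
    bindings <- if (ncol(bindings) == 0 || all(names(bindings) == ".rows")) m
    else if (length(shared) > 0) dplyr::inner_join(bindings, m, by = shared)
    else dplyr::cross_join(bindings, m)
    if (nrow(bindings) == 0) break
  }
  if (".rows" %in% names(bindings)) bindings$.rows <- NULL
  for (f in q$filters) {
    if (nrow(bindings) == 0) break
    bindings <- bindings[eval_filter(f, bindings, q$prefixes, ns), , drop = FALSE]
  }
  vars <- if (q$star) names(bindings) else q$vars
  missing_vars <- setdiff(vars, names(bindings))
  for (v in missing_vars) bindings[[v]] <- character(nrow(bindings))
  rows <- bindings[, vars, drop = FALSE]
  if (q$distinct) rows <- dplyr::distinct(rows)
  if (is.null(subject_var)) subject_var <- vars[1]
  new_query_result(vars, rows, subject_var)
}

new_query_result <- function(variables, rows, subject_var) {
  ds <- if (!is.null(subject_var) && length(variables) > 0 && subject_var %in% variables) {
    length(unique(rows[[subject_var]]))
  } else 0L
  structure(list(variables = variables, rows = tibble::as_tibble(rows),
                 subject_var = subject_var, distinct_subjects = ds),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("Query result: %d row(s), %d distinct subject(s) [?%s]\n",
              nrow(x$rows), x$distinct_subjects, x$subject_var))
  print(x$rows, n = 10)
  invisible(x)
}

#' Describe resources: all statements about a set of subjects
#'
#' Implements the describe form used for query-refinement exploration.
#' `mode = "symmetric"` (the default symmetric concise bounded description)
#' returns statements where the resource appears as subject or as object;
#' `mode = "forward"` restricts to outgoing statements.
#'
#' @param graph A `sbpkb_graph`.
#' @param subjects Character vector of prefixed resource names.
#' @param mode `"symmetric"` or `"forward"`.
#' @return Statement tibble.
#' @export
sbpkb_describe <- function(graph, subjects, mode = c("symmetric", "forward")) {
  mode <- match.arg(mode)
  st <- graph$statements
  keep <- st$subject %in% subjects
  if (mode == "symmetric") {
    keep <- keep | (st$object_type == "uri" & st$object %in% subjects)
  }
  canonical_statements(st[keep, ])
}
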