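expand_iri <- function(x, ns) {
  pfx <- sub(":.*$", "", x)
  local <- sub("^[^:]*:", "", x)
  if (!pfx %in% names(ns)) stop(sprintf("unknown namespace prefix '%s'", pfx), call. = FALSE)
  paste0(ns[[pfx]], local)
}

contract_iri <- function(x, ns) {
  for (pfx in names(ns)) {
    if (startsWith(x, ns[[pfx]])) {
      return(paste0(pfx, ":", substring(x, nchar(ns[[pfx]]) + 1)))
    }
  }
  stop(sprintf("IRI '%s' does not match any declared namespace", x), call. = FALSE)
}

escape_turtle <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_turtle <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "")[[1]]
    buf <- character(0)
    j <- 1
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t", nxt))
        j <- j + 2
      } else {
        buf <- c(buf, chars[j])
        j <- j + 1
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

turtle_object <- function(object, object_type) {
  ifelse(object_type == "uri", object,
         ifelse(object_type == "integer", object,
                paste0('"', escape_turtle(object), '"')))
}

write_turtle <- function(graph, path) {
  st <- canonical_statements(graph$statements)
  ns <- graph$namespaces
  header <- sprintf("@prefix %s: <%s> .", names(ns), unname(ns))
  body <- sprintf("%s %s %s .", st$subject, st$predicate,
                  turtle_object(st$object, st$object_type))
  writeLines(c(header, "", body), path, useBytes = TRUE)
  invisible(path)
}

read_turtle <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ns_lines <- grepl("^@prefix ", lines)
  m <- regmatches(lines[ns_lines],
                  regexec("^@prefix ([A-Za-z][A-Za-z0-9]*): <([^>]*)> \\.$", lines[ns_lines]))
  ns <- stats::setNames(vapply(m, `[`, character(1), 3),
                        vapply(m, `[`, character(1), 2))
  triples <- lines[!ns_lines]
  parse_one <- function(line) {
    rest <- trimws(line)
    sp <- regexec("^(\\S+)\\s+(\\S+)\\s+(.*)\\s*\\.$", rest)[[1]]
    if (sp[1] == -1) stop(sprintf("cannot parse Turtle triple: %s", line), call. = FALSE)
    parts <- regmatches(rest, regexec("^(\\S+)\\s+(\\S+)\\s+(.*?)\\s*\\.$", rest))[[1]]
    obj_tok <- parts[4]
    if (startsWith(obj_tok, '"')) {
      inner <- regmatches(obj_tok, regexec('^"((?:[^"\\\\]|\\\\.)*)"$', obj_tok))[[1]]
      if (length(inner) == 0) stop(sprintf("bad literal in: %s", line), call. = FALSE)
      obj <- unescape_turtle(inner[2]); typ <- "string"
    } else if (grepl("^-?[0-9]+$", obj_tok)) {
      obj <- obj_tok; typ <- "integer"
    } else if (startsWith(obj_tok, "<")) {
      obj <- contract_iri(sub("^<(.*)>$", "\\1", obj_tok), ns); typ <- "uri"
    } else {
      obj <- obj_tok; typ <- "uri"
    }
    list(subject = parts[2], predicate = parts[3], object = obj, object_type = typ)
  }
  rows <- lapply(triples, parse_one)
  st <- if (length(rows) == 0) new_statements() else dplyr::bind_rows(rows)
  structure(list(statements = canonical_statements(st), namespaces = ns,
                 provenance = paste0("parsed from ", basename(path))),
            class = "sbpkb_graph")
}

write_rdfxml <- function(graph, path) {
  st <- canonical_statements(graph$statements)
  ns <- graph$namespaces
  attrs <- stats::setNames(as.list(unname(ns)), paste0("xmlns:", names(ns)))
  doc <- do.call(xml2::xml_new_root, c(list("rdf:RDF"), attrs))
  for (subj in unique(st$subject)) {
    desc <- xml2::xml_add_child(doc, "rdf:Description",
                                "rdf:about" = expand_iri(subj, ns))
    rows <- st[st$subject == subj, ]
    for (i in seq_len(nrow(rows))) {
      if (rows$object_type[i] == "uri") {
        xml2::xml_add_child(desc, rows$predicate[i],
                            "rdf:resource" = expand_iri(rows$object[i], ns))
      } else if (rows$object_type[i] == "integer") {
        xml2::xml_add_child(desc, rows$predicate[i], rows$object[i],
                            "rdf:datatype" = expand_iri("xsd:integer", ns))
      } else {
        xml2::xml_add_child(desc, rows$predicate[i], rows$object[i])
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_rdfxml <- function(path) {
  doc <- xml2::read_xml(path)
  ns_map <- xml2::xml_ns(doc)
  # xml_ns returns prefix -> IRI as declared on the document
  ns <- stats::setNames(as.character(ns_map), names(ns_map))
  rows <- list()
  for (desc in xml2::xml_children(doc)) {
    subj <- contract_iri(xml2::xml_attr(desc, "about"), ns)
    for (prop in xml2::xml_children(desc)) {
      pred <- xml2::xml_name(prop, ns = ns_map)
      resource <- xml2::xml_attr(prop, "resource")
      datatype <- xml2::xml_attr(prop, "datatype")
      if (!is.na(resource)) {
        rows[[length(rows) + 1]] <- list(subject = subj, predicate = pred,
                                         object = contract_iri(resource, ns),
                                         object_type = "uri")
      } else if (!is.na(datatype) && endsWith(datatype, "integer")) {
        rows[[length(rows) + 1]] <- list(subject = subj, predicate = pred,
                                         object = xml2::xml_text(prop),
                                         object_type = "integer")
      } else {
        rows[[length(rows) + 1]] <- list(subject = subj, predicate = pred,
                                         object = xml2::xml_text(prop),
                                         object_type = "string")
      }
    }
  }
  st <- if (length(rows) == 0) new_statements() else dplyr::bind_rows(rows)
  structure(list(statements = canonical_statements(st), namespaces = ns,
                 provenance = paste0("parsed from ", basename(path))),
            class = "sbpkb_graph")
}

#' Serialize / parse a knowledge graph
#'
#' Turtle output is canonically ordered (sorted prefixes then sorted triples),
#' so identical graphs serialize to byte-identical files. Both formats
#' round-trip: parsing a serialized file reproduces the original statement
#' set exactly.
#'
#' @param graph A `sbpkb_graph`.
#' @param path Output (input) file path.
#' @param format `"turtle"` or `"rdfxml"`.
#' @return `serialize_graph`: `path` invisibly. `read_graph`: a `sbpkb_graph`.
#' @export
serialize_graph <- function(graph, path, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  switch(format, turtle = write_turtle(graph, path), rdfxml = write_rdfxml(graph, path))
}

#' @rdname serialize_graph
#' @export
read_graph <- function(path, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  switch(format, turtle = read_turtle(path), rdfxml = read_rdfxml(path))
}
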