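# Triple-store container for the knowledge graph, with N-Triples / Turtle
# serialization and parsing.
#
# Internal token convention: individuals are full URIs in the data
# namespace; classes and properties are compact schema ids (expanded to the
# schema namespace on serialization); rdf:type and rdfs:label are the two
# reserved predicates.

RNAKB_DATA_NS <- "http://rnakb.local/id/"
RNAKB_SCHEMA_NS <- "http://rnakb.local/schema/"
RDF_TYPE_URI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL_URI <- "http://www.w3.org/2000/01/rdf-schema#label"

empty_triples <- function() {
  data.frame(s = character(0), p = character(0), o = character(0),
             lit = logical(0), stringsAsFactors = FALSE)
}

#' Construct a knowledge graph from a triple table
#'
#' Triples are held as a duplicate-free set; the label index (from
#' `rdfs:label` triples) and the type index (from `rdf:type` triples) are
#' rebuilt on construction.
#'
#' @param triples Data frame with columns `s`, `p`, `o`, `lit` (logical:
#'   object is a literal).
#' @param ns Data namespace used when minting individual URIs.
#' @return A `kb_graph`.
#' @export
kb_graph <- function(triples = empty_triples(), ns = RNAKB_DATA_NS) {
  triples <- triples[!duplicated(triple_keys(triples)), , drop = FALSE]
  rownames(triples) <- NULL
  g <- structure(list(triples = triples, ns = ns,
                      label_index = character(0), type_index = list()),
                 class = "kb_graph")
  reindex_graph(g)
}

triple_keys <- function(triples) {
  paste(triples$s, triples$p, triples$o, triples$lit, sep = "\r")
}

reindex_graph <- function(g) {
  tr <- g$triples
  lab <- tr[tr$p == "rdfs:label" & tr$lit, , drop = FALSE]
  g$label_index <- stats::setNames(lab$s, lab$o)
  ty <- tr[tr$p == "rdf:type" & !tr$lit, , drop = FALSE]
  g$type_index <- split(ty$o, ty$s)
  g
}

#' @export
print.kb_graph <- function(x, ...) {
  cat(sprintf("<kb graph: %d triples, %d typed individuals, %d labels>\n",
              nrow(x$triples), length(x$type_index),
              length(x$label_index)))
  invisible(x)
}

#' Number of triples in a graph
#' @param g A `kb_graph`.
#' @return Integer count.
#' @export
graph_size <- function(g) nrow(g$triples)

#' Individuals asserted to be instances of a class
#' @param g A `kb_graph` (saturate first for inferred types).
#' @param class_id Schema class id.
#' @return Sorted character vector of URIs.
#' @export
instances_of <- function(g, class_id) {
  hits <- vapply(g$type_index, function(ts) class_id %in% ts, TRUE)
  sort(names(g$type_index)[hits])
}

add_triples <- function(g, triples) {
  all_tr <- rbind(g$triples, triples)
  all_tr <- all_tr[!duplicated(triple_keys(all_tr)), , drop = FALSE]
  rownames(all_tr) <- NULL
  g$triples <- all_tr
  reindex_graph(g)
}

# --- serialization ----------------------------------------------------------

expand_token <- function(token, is_literal = FALSE) {
  if (is_literal) return(token)
  if (token == "rdf:type") return(RDF_TYPE_URI)
  if (token == "rdfs:label") return(RDFS_LABEL_URI)
  if (grepl("^[a-z][a-z0-9+.-]*://", token)) return(token)
  paste0(RNAKB_SCHEMA_NS, token)
}

compact_token <- function(uri) {
  if (uri == RDF_TYPE_URI) return("rdf:type")
  if (uri == RDFS_LABEL_URI) return("rdfs:label")
  if (startsWith(uri, RNAKB_SCHEMA_NS)) {
    return(substring(uri, nchar(RNAKB_SCHEMA_NS) + 1))
  }
  uri
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub('\\"', '"', x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Serialize a knowledge graph
#'
#' Writes sorted, deterministic N-Triples or Turtle (one triple per line;
#' the Turtle dialect uses `rkb:` for the schema namespace and `d:` for the
#' data namespace).
#'
#' @param g A `kb_graph`.
#' @param format `"ntriples"` or `"turtle"`.
#' @param path Optional file path; when given, lines are written there.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
serialize_graph <- function(g, format = c("ntriples", "turtle"),
                            path = NULL) {
  format <- match.arg(format)
  tr <- g$triples
  ord <- order(tr$s, tr$p, tr$o)
  tr <- tr[ord, , drop = FALSE]
  if (nrow(tr) == 0 && format == "ntriples") {
    lines <- character(0)
    if (!is.null(path)) {
      writeLines(lines, path)
      return(invisible(lines))
    }
    return(lines)
  }
  if (format == "ntriples") {
    obj <- ifelse(tr$lit, paste0('"', escape_literal(tr$o), '"'),
                  paste0("<", vapply(tr$o, expand_token, ""), ">"))
    lines <- paste0("<", vapply(tr$s, expand_token, ""), "> <",
                    vapply(tr$p, expand_token, ""), "> ", obj, " .")
  } else {
    prefixes <- c(
      paste0("@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> ."),
      paste0("@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> ."),
      paste0("@prefix rkb: <", RNAKB_SCHEMA_NS, "> ."),
      paste0("@prefix d: <", g$ns, "> .")
    )
    qn <- function(tok) {
      uri <- expand_token(tok)
      if (startsWith(uri, g$ns)) {
        local <- substring(uri, nchar(g$ns) + 1)
        if (grepl("^[A-Za-z0-9_.-]+$", local)) return(paste0("d:", local))
      }
      if (startsWith(uri, RNAKB_SCHEMA_NS)) {
        local <- substring(uri, nchar(RNAKB_SCHEMA_NS) + 1)
        if (grepl("^[A-Za-z0-9_.-]+$", local)) return(paste0("rkb:", local))
      }
      if (uri == RDF_TYPE_URI) return("rdf:type")
      if (uri == RDFS_LABEL_URI) return("rdfs:label")
      paste0("<", uri, ">")
    }
    obj <- ifelse(tr$lit, paste0('"', escape_literal(tr$o), '"'),
                  vapply(tr$o, qn, ""))
    lines <- c(prefixes, "",
               paste0(vapply(tr$s, qn, ""), " ", vapply(tr$p, qn, ""), " ",
                      obj, " ."))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a serialized knowledge graph
#'
#' Reads the N-Triples / line-oriented Turtle emitted by
#' [serialize_graph()] (one triple per line, `@prefix` declarations,
#' prefixed names or full IRIs, plain string literals) back into a
#' `kb_graph` with set semantics (duplicates collapse).
#'
#' @param input Path to a file, or character vector of lines.
#' @param format `"ntriples"` or `"turtle"`.
#' @return A `kb_graph`.
#' @export
parse_graph <- function(input, format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  prefixes <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                rdfs = "http://www.w3.org/2000/01/rdf-schema#")
  ns <- RNAKB_DATA_NS
  rows <- vector("list", length(lines))
  n <- 0
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line,
                      regexec("^@prefix\\s+([A-Za-z0-9_]*):\\s*<([^>]*)>\\s*\\.$",
                              line))[[1]]
      if (length(m) != 3) stop("malformed @prefix at line ", i)
      prefixes[m[2]] <- m[3]
      if (m[2] == "d") ns <- m[3]
      next
    }
    toks <- tokenize_triple_line(line, i)
    if (length(toks) != 3) {
      stop("expected 3 terms in triple at line ", i)
    }
    term <- function(tok) {
      if (tok$kind == "iri") {
        return(list(v = compact_token(tok$value), lit = FALSE))
      }
      if (tok$kind == "qname") {
        pre <- prefixes[tok$prefix]
        if (is.na(pre)) stop("unknown prefix '", tok$prefix, "' at line ", i)
        return(list(v = compact_token(paste0(pre, tok$value)), lit = FALSE))
      }
      list(v = unescape_literal(tok$value), lit = TRUE)
    }
    s <- term(toks[[1]]); p <- term(toks[[2]]); o <- term(toks[[3]])
    if (s$lit || p$lit) stop("literal in subject/predicate position at line ", i)
    n <- n + 1
    rows[[n]] <- data.frame(s = s$v, p = p$v, o = o$v, lit = o$lit,
                            stringsAsFactors = FALSE)
  }
  triples <- if (n) do.call(rbind, rows[seq_len(n)]) else empty_triples()
  kb_graph(triples, ns = ns)
}

# Split one "<s> <p> <o|literal> ." line into three typed tokens.
tokenize_triple_line <- function(line, lineno) {
  if (!grepl("\\.$", line)) stop("triple not terminated by '.' at line ", lineno)
  body <- trimws(sub("\\.$", "", line))
  toks <- list()
  i <- 1
  nch <- nchar(body)
  while (i <= nch) {
    ch <- substr(body, i, i)
    if (ch == " " || ch == "\t") { i <- i + 1; next }
    if (ch == "<") {
      j <- regexpr(">", substr(body, i, nch), fixed = TRUE)
      if (j < 0) stop("unterminated IRI at line ", lineno)
      toks[[length(toks) + 1]] <- list(kind = "iri",
                                       value = substr(body, i + 1, i + j - 2))
      i <- i + j
    } else if (ch == '"') {
      j <- i + 1
      while (j <= nch) {
        cj <- substr(body, j, j)
        if (cj == "\\") { j <- j + 2; next }
        if (cj == '"') break
        j <- j + 1
      }
      if (j > nch) stop("unterminated literal at line ", lineno)
      toks[[length(toks) + 1]] <- list(kind = "literal",
                                       value = substr(body, i + 1, j - 1))
      i <- j + 1
    } else {
      j <- regexpr("[ \t]", substr(body, i, nch))
      end <- if (j < 0) nch else i + j - 2
      word <- substr(body, i, end)
      m <- regmatches(word, regexec("^([A-Za-z0-9_]*):(.*)$", word))[[1]]
      if (length(m) == 3) {
        toks[[length(toks) + 1]] <- list(kind = "qname", prefix = m[2],
                                         value = m[3])
      } else {
        stop("unparseable term '", word, "' at line ", lineno)
      }
      i <- end + 1
    }
  }
  toks
}
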