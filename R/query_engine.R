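# Class-expression queries: a Manchester-syntax subset parser, closed-world
# saturation (materialization) and a set-based evaluator.
#
# The supported fragment is positive existential: named classes, `and`
# (also written `that`), `or`, `some`, `exactly n`, `inv(p)`, nominals
# `{'label'}` and parentheses, with the usual precedence
# (some/exactly > and > or). Evaluation is closed-world over the saturated
# graph, with one TBox shortcut: an individual typed C where the schema
# asserts C SubClassOf (p some D) satisfies `p some E` whenever D is a
# subclass of a named disjunct of E. For this fragment the shortcut yields
# the answers a description-logic reasoner certifies, without materializing
# anonymous individuals.

# --- tokenizer --------------------------------------------------------------

tokenize_expression <- function(text) {
  toks <- list()
  i <- 1
  n <- nchar(text)
  push <- function(kind, value, pos) {
    toks[[length(toks) + 1]] <<- list(kind = kind, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1; next }
    if (ch == "'") {
      j <- i + 1
      while (j <= n && substr(text, j, j) != "'") j <- j + 1
      if (j > n) stop("unbalanced quote starting at position ", i)
      push("label", substr(text, i + 1, j - 1), i)
      i <- j + 1
    } else if (ch %in% c("(", ")", "{", "}", ",")) {
      push(ch, ch, i)
      i <- i + 1
    } else {
      m <- regexpr("^[A-Za-z0-9_']+", substr(text, i, n))
      if (m < 0) stop("unexpected character '", ch, "' at position ", i)
      word <- regmatches(substr(text, i, n), m)
      if (grepl("^[0-9]+$", word)) {
        push("int", as.integer(word), i)
      } else if (word %in% c("that", "and", "or", "some", "exactly", "inv")) {
        push(word, word, i)
      } else {
        push("word", word, i)
      }
      i <- i + nchar(word)
    }
  }
  toks
}

# --- recursive-descent parser ----------------------------------------------

#' Parse a Manchester-syntax class expression
#'
#' Grammar: quoted (`'structure model'`) or bare (`externally_connected_to`)
#' labels; `that`/`and` (synonymous conjunction); `or`; `p some E`;
#' `p exactly n E`; `inv(p)` for the inverse property; nominals
#' `{'label', ...}`; parentheses. Restrictions bind tighter than `and`,
#' which binds tighter than `or`.
#'
#' @param text Expression text.
#' @return A class-expression AST (nested lists with a `kind` field).
#' @export
parse_class_expression <- function(text) {
  toks <- tokenize_expression(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() { t <- peek(); st$i <- st$i + 1; t }
  expect <- function(kind) {
    t <- peek()
    if (is.null(t) || t$kind != kind) {
      stop("expected '", kind, "' at position ",
           if (is.null(t)) nchar(text) + 1 else t$pos)
    }
    advance()
  }

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && peek()$kind == "or") {
      advance()
      args[[length(args) + 1]] <- parse_and()
    }
    if (length(args) == 1) args[[1]] else list(kind = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_unit())
    while (!is.null(peek()) && peek()$kind %in% c("and", "that")) {
      advance()
      args[[length(args) + 1]] <- parse_unit()
    }
    if (length(args) == 1) args[[1]] else list(kind = "and", args = args)
  }
  parse_unit <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of expression")
    if (t$kind == "(") {
      advance()
      e <- parse_or()
      expect(")")
      return(maybe_restriction_of(e, t$pos))
    }
    if (t$kind == "{") {
      advance()
      labels <- character(0)
      repeat {
        lt <- peek()
        if (is.null(lt) || !(lt$kind %in% c("label", "word"))) {
          stop("expected individual label in nominal at position ",
               if (is.null(lt)) nchar(text) + 1 else lt$pos)
        }
        advance()
        labels <- c(labels, lt$value)
        if (!is.null(peek()) && peek()$kind == ",") { advance(); next }
        break
      }
      expect("}")
      return(list(kind = "nominal", labels = labels))
    }
    if (t$kind == "inv") {
      advance(); expect("(")
      pt <- peek()
      if (is.null(pt) || !(pt$kind %in% c("label", "word"))) {
        stop("expected property label inside inv() at position ",
             if (is.null(pt)) nchar(text) + 1 else pt$pos)
      }
      advance(); expect(")")
      return(parse_restriction(pt$value, inverse = TRUE, pos = t$pos))
    }
    if (t$kind %in% c("label", "word")) {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$kind %in% c("some", "exactly")) {
        return(parse_restriction(t$value, inverse = FALSE, pos = t$pos))
      }
      return(list(kind = "named", label = t$value))
    }
    stop("unexpected token '", t$value, "' at position ", t$pos)
  }
  parse_restriction <- function(property, inverse, pos) {
    t <- peek()
    if (is.null(t) || !(t$kind %in% c("some", "exactly"))) {
      stop("expected 'some' or 'exactly' after property at position ",
           if (is.null(t)) nchar(text) + 1 else t$pos)
    }
    advance()
    if (t$kind == "some") {
      list(kind = "some", property = property, inverse = inverse,
           filler = parse_unit())
    } else {
      nt <- expect("int")
      list(kind = "exactly", n = nt$value, property = property,
           inverse = inverse, filler = parse_unit())
    }
  }
  # a parenthesized expression is a plain operand (never a property)
  maybe_restriction_of <- function(e, pos) e

  out <- parse_or()
  if (!is.null(peek())) {
    stop("trailing input at position ", peek()$pos)
  }
  out
}

# --- saturation -------------------------------------------------------------

#' Saturate (materialize) a knowledge graph against the schema
#'
#' Computes the fixed point of: type closure (instances inherit all
#' superclasses, including membership in agglomerating union classes),
#' sub-property closure ('has proper part' entails 'has part'), inverse
#' closure for all declared inverse pairs, symmetric closure ('externally
#' connected to') and transitive closure ('part of' / 'has part').
#' Idempotent.
#'
#' @param g A `kb_graph`.
#' @param schema A `schema_catalog`.
#' @return The saturated `kb_graph`.
#' @export
saturate <- function(g, schema = load_schema()) {
  super_map <- lapply(stats::setNames(names(schema$classes),
                                      names(schema$classes)),
                      function(cid) superclasses_of(schema, cid))
  props <- schema$properties
  tr <- g$triples
  repeat {
    before <- nrow(tr)
    new_rows <- list()
    # sub-property closure
    for (pid in names(props)) {
      for (parent in props[[pid]]$parents) {
        sub <- tr[tr$p == pid, , drop = FALSE]
        if (nrow(sub)) {
          sub$p <- parent
          new_rows[[length(new_rows) + 1]] <- sub
        }
      }
    }
    # inverse closure
    for (pid in names(props)) {
      inv <- props[[pid]]$inverse
      if (is.null(inv)) next
      sub <- tr[tr$p == pid & !tr$lit, , drop = FALSE]
      if (nrow(sub)) {
        new_rows[[length(new_rows) + 1]] <-
          data.frame(s = sub$o, p = inv, o = sub$s, lit = FALSE,
                     stringsAsFactors = FALSE)
      }
    }
    # symmetric closure
    for (pid in names(props)) {
      if (!props[[pid]]$symmetric) next
      sub <- tr[tr$p == pid & !tr$lit, , drop = FALSE]
      if (nrow(sub)) {
        new_rows[[length(new_rows) + 1]] <-
          data.frame(s = sub$o, p = pid, o = sub$s, lit = FALSE,
                     stringsAsFactors = FALSE)
      }
    }
    # transitive closure (inner fixed point per property)
    for (pid in names(props)) {
      if (!props[[pid]]$transitive) next
      edges <- unique(tr[tr$p == pid & !tr$lit, c("s", "o"), drop = FALSE])
      if (nrow(edges) == 0) next
      closed <- transitive_close(edges)
      if (nrow(closed) > nrow(edges)) {
        new_rows[[length(new_rows) + 1]] <-
          data.frame(s = closed$s, p = pid, o = closed$o, lit = FALSE,
                     stringsAsFactors = FALSE)
      }
    }
    # type closure
    ty <- tr[tr$p == "rdf:type" & !tr$lit, , drop = FALSE]
    if (nrow(ty)) {
      known <- ty$o %in% names(super_map)
      ups <- super_map[ty$o[known]]
      reps <- lengths(ups)
      new_rows[[length(new_rows) + 1]] <-
        data.frame(s = rep(ty$s[known], reps), p = "rdf:type",
                   o = unlist(ups, use.names = FALSE), lit = FALSE,
                   stringsAsFactors = FALSE)
    }
    if (length(new_rows)) {
      tr <- rbind(tr, do.call(rbind, new_rows))
      tr <- tr[!duplicated(triple_keys(tr)), , drop = FALSE]
    }
    if (nrow(tr) == before) break
  }
  rownames(tr) <- NULL
  g$triples <- tr
  reindex_graph(g)
}

# Transitive closure of an edge list (data.frame s, o) by repeated join.
transitive_close <- function(edges) {
  repeat {
    joined <- merge(edges, edges, by.x = "o", by.y = "s")
    if (nrow(joined)) {
      cand <- data.frame(s = joined$s, o = joined$o.y,
                         stringsAsFactors = FALSE)
      cand <- cand[cand$s != cand$o, , drop = FALSE]
      allp <- rbind(edges, cand)
      allp <- allp[!duplicated(paste(allp$s, allp$o, sep = "\r")), ,
                   drop = FALSE]
      if (nrow(allp) == nrow(edges)) return(edges)
      edges <- allp
    } else {
      return(edges)
    }
  }
}

# --- evaluation -------------------------------------------------------------

resolve_property <- function(label, schema) {
  id <- schema$label_to_id[label]
  if (is.na(id)) id <- schema$label_to_id[gsub("_", " ", label)]
  if (is.na(id) || is.null(schema$properties[[id]])) {
    stop("unresolved property label: '", label, "'")
  }
  unname(id)
}

# Named class labels usable for the TBox shortcut: a named filler or the
# named disjuncts of a union. NULL when none exist.
named_disjuncts <- function(expr) {
  if (expr$kind == "named") return(expr$label)
  if (expr$kind == "or") {
    labs <- unlist(lapply(expr$args, function(a)
      if (a$kind == "named") a$label else NULL))
    return(labs)
  }
  NULL
}

#' Evaluate a class expression over a saturated knowledge graph
#'
#' Closed-world, set-based semantics: a named class denotes the individuals
#' carrying its type; `and`/`or` intersect/unite; a nominal denotes the
#' listed individuals; `p some E` holds for subjects with a `p`-filler in E
#' or (TBox shortcut) whose asserted class carries an existential axiom
#' `C SubClassOf p some D` with D below a named disjunct of E; `p exactly n
#' E` counts asserted+saturated `p`-fillers in E.
#'
#' @param expr Expression text or AST from [parse_class_expression()].
#' @param g A saturated `kb_graph` (see [saturate()]).
#' @param schema A `schema_catalog`.
#' @return A `query_result`: list with sorted `individuals` and
#'   `cardinality`.
#' @export
evaluate_expression <- function(expr, g, schema = load_schema()) {
  if (is.character(expr)) expr <- parse_class_expression(expr)
  individuals <- sort(evaluate_node(expr, g, schema))
  structure(list(individuals = individuals,
                 cardinality = length(individuals)),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query result: %d individual(s)>\n", x$cardinality))
  if (x$cardinality) cat(paste0("  ", x$individuals, collapse = "\n"), "\n")
  invisible(x)
}

evaluate_node <- function(expr, g, schema) {
  switch(
    expr$kind,
    named = {
      id <- resolve_label(expr$label, schema, g)
      if (!is.null(schema$classes[[id]])) {
        instances_of(g, id)
      } else {
        # a label naming an individual denotes that singleton
        id
      }
    },
    and = Reduce(intersect, lapply(expr$args, evaluate_node, g = g,
                                   schema = schema)),
    or = Reduce(union, lapply(expr$args, evaluate_node, g = g,
                              schema = schema)),
    nominal = vapply(expr$labels, function(l) resolve_label(l, schema, g),
                     "", USE.NAMES = FALSE),
    some = {
      pid <- resolve_property(expr$property, schema)
      fill <- evaluate_node(expr$filler, g, schema)
      sub <- g$triples[g$triples$p == pid & !g$triples$lit, , drop = FALSE]
      subj <- if (expr$inverse) sub$o[sub$s %in% fill]
              else sub$s[sub$o %in% fill]
      out <- unique(subj)
      if (!expr$inverse) {
        ax <- schema$existential_axioms
        ax <- ax[ax$prop == pid, , drop = FALSE]
        if (nrow(ax)) {
          nd <- named_disjuncts(expr$filler)
          if (is.null(nd)) {
            stop("unsupported expression: existential axioms exist for '",
                 expr$property,
                 "' but the filler has no named disjunct to match")
          }
          nd_ids <- vapply(nd, function(l) resolve_label(l, schema, g), "")
          nd_ids <- nd_ids[nd_ids %in% names(schema$classes)]
          for (k in seq_len(nrow(ax))) {
            if (any(nd_ids %in% superclasses_of(schema, ax$filler[k]))) {
              out <- union(out, instances_of(g, ax$subclass[k]))
            }
          }
        }
      }
      out
    },
    exactly = {
      pid <- resolve_property(expr$property, schema)
      fill <- evaluate_node(expr$filler, g, schema)
      sub <- g$triples[g$triples$p == pid & !g$triples$lit, , drop = FALSE]
      if (expr$inverse) sub <- data.frame(s = sub$o, o = sub$s,
                                          stringsAsFactors = FALSE)
      sub <- sub[sub$o %in% fill, , drop = FALSE]
      counts <- table(sub$s)
      domain <- names(g$type_index)
      cnt <- stats::setNames(rep(0L, length(domain)), domain)
      cnt[names(counts)] <- as.integer(counts)
      names(cnt)[cnt == expr$n]
    },
    stop("unknown expression node kind: ", expr$kind)
  )
}

# --- stored query templates -------------------------------------------------

HOOGSTEEN_CLAUSE <- paste0(
  "('hoogsteen edge' or 'part of' some 'hoogsteen edge') and ",
  "externally_connected_to some ",
  "('nucleotide edge' or 'part of' some 'nucleotide edge')")

STORED_QUERY_TEMPLATES <- list(
  A = "'structure model' that 'is represented by' some {'Molecular Structure File PDB:%s'}",
  B = paste0("'nucleotide base pair' that 'has part' some (",
             HOOGSTEEN_CLAUSE, ")"),
  C = paste0("'nucleotide base pair' that 'has part' some (",
             "('hoogsteen edge' or 'part of' some 'hoogsteen edge') and ",
             "'part of' some 'GMP residue [chebi:50324]' and ",
             "externally_connected_to some ",
             "('nucleotide edge' or 'part of' some 'nucleotide edge'))"),
  D = paste0("'nucleotide base pair' that ('has part' some ",
             "('watson watson sub edge' and externally_connected_to some ",
             "'hoogsteen hoogsteen sub edge'))"),
  E = paste0("'nucleotide base pair' that 'has part' some (",
             HOOGSTEEN_CLAUSE, ") and inv('is about') some ",
             "('structure model' that 'is represented by' some ",
             "{'Molecular Structure File PDB:%s'})"),
  F = "'structure model' that 'is represented by' some {'Molecular Structure File PDB:%s'}"
)

#' Text of a stored query template
#' @param which Query letter `"A"`-`"F"`.
#' @param pdb_id PDB identifier substituted into the file nominal
#'   (lowercased).
#' @return The query text.
#' @export
stored_query_text <- function(which, pdb_id = "1am0") {
  tmpl <- STORED_QUERY_TEMPLATES[[toupper(which)]]
  if (is.null(tmpl)) stop("unknown query: ", which)
  if (grepl("%s", tmpl, fixed = TRUE)) {
    tmpl <- gsub("%s", tolower(pdb_id), tmpl, fixed = TRUE)
  }
  tmpl
}

#' Run one of the stored catalog queries (A-F)
#'
#' A/F count structure models of a file; B finds base pairs involving a
#' Hoogsteen edge (through the sub-edge agglomeration axioms); C restricts
#' B to Hoogsteen edges on guanosine residues; D finds Watson-Watson /
#' Hoogsteen-Hoogsteen sub-edge interactions; E scopes B to the models of
#' one file.
#'
#' @param which Query letter `"A"`-`"F"`.
#' @param g A saturated `kb_graph`.
#' @param schema A `schema_catalog`.
#' @param pdb_id PDB identifier substituted into the template.
#' @return A `query_result`.
#' @export
run_stored_query <- function(which, g, schema = load_schema(),
                            pdb_id = "1am0") {
  evaluate_expression(stored_query_text(which, pdb_id), g, schema)
}
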