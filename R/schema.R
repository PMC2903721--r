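# Bundled static ontology catalog: the classes, properties and axioms the
# knowledge graph is typed against. The catalog is a minimal-import style
# subset (material entities, qualities, information content entities,
# nucleotide edges/sub-edges with their agglomeration axioms) shipped with
# the package; external ontology identifiers are kept as cross-references.

schema_id <- function(label) {
  id <- gsub("[^A-Za-z0-9]+", "_", label)
  gsub("^_+|_+$", "", id)
}

# Sub-edge token -> class label.
SUBEDGE_CLASS_LABEL <- c(
  Ww = "watson watson sub edge", Wh = "watson hoogsteen sub edge",
  Ws = "watson sugar sub edge", Bw = "bifurcated watson sub edge",
  Hh = "hoogsteen hoogsteen sub edge", Hw = "hoogsteen watson sub edge",
  Bh = "bifurcated hoogsteen sub edge", C8 = "C8 sub edge",
  Ss = "sugar sugar sub edge", Sw = "sugar watson sub edge",
  Bs = "bifurcated sugar sub edge", O2p = "O2' sub edge"
)

EDGE_CLASS_LABEL <- c(WatsonCrick = "watson-crick edge",
                      Hoogsteen = "hoogsteen edge",
                      Sugar = "sugar edge")

AGGLOMERATE_LABEL <- c(WatsonCrick = "watson sub-edge",
                       Hoogsteen = "hoogsteen sub-edge",
                       Sugar = "sugar sub-edge")

RESIDUE_CLASS_LABEL <- c(A = "AMP residue", C = "CMP residue",
                         G = "GMP residue [chebi:50324]", U = "UMP residue",
                         modified = "nucleotide residue")

#' Load the bundled schema catalog
#'
#' Builds the static catalog of named classes (with subclass hierarchy and
#' the sub-edge agglomeration equivalences), properties (inverses,
#' transitivity, symmetry, sub-properties) and existential axioms (each
#' agglomerating sub-edge class is part of its Leontis-Westhof edge class).
#'
#' @return A `schema_catalog`: list with `classes`, `properties`,
#'   `existential_axioms` and a `label_to_id` lookup.
#' @export
load_schema <- function() {
  cls <- list()
  add_class <- function(label, parents = character(0),
                        equivalent_union = NULL, xref = NULL) {
    id <- schema_id(label)
    if (!is.null(cls[[id]])) stop("duplicate schema label/id: ", label)
    cls[[id]] <<- list(label = label,
                       parents = vapply(parents, schema_id, ""),
                       equivalent_union = equivalent_union, xref = xref)
    id
  }

  add_class("material entity")
  add_class("quality")
  add_class("information content entity")
  add_class("molecular structure file", "information content entity")
  add_class("structure model", "information content entity")

  add_class("molecule", "material entity")
  add_class("nucleotide residue", "material entity", xref = "CHEBI:50319")
  add_class("AMP residue", "nucleotide residue")
  add_class("CMP residue", "nucleotide residue")
  add_class("GMP residue [chebi:50324]", "nucleotide residue",
            xref = "CHEBI:50324")
  add_class("UMP residue", "nucleotide residue")
  add_class("nucleoside", "material entity", xref = "RKB:000027")
  add_class("ribose", "material entity")
  add_class("nucleobase", "material entity")
  add_class("atom", "material entity")
  add_class("nucleotide base pair", "material entity")
  add_class("nucleotide base stack", "material entity")

  add_class("nucleotide edge", "material entity")
  for (lab in EDGE_CLASS_LABEL) add_class(lab, "nucleotide edge")

  add_class("nucleotide sub-edge", "material entity")
  members <- split(SUBEDGE_CLASS_LABEL, SUBEDGE_TO_EDGE[names(SUBEDGE_CLASS_LABEL)])
  for (edge in names(AGGLOMERATE_LABEL)) {
    agg <- AGGLOMERATE_LABEL[[edge]]
    add_class(agg, "nucleotide sub-edge",
              equivalent_union = vapply(unname(members[[edge]]), schema_id, ""),
              xref = if (edge == "Hoogsteen") "RKB:000092" else NULL)
    for (m in members[[edge]]) add_class(m, agg)
  }

  for (lab in c("syn conformation", "anti conformation", "endo", "exo",
                "envelope conformation", "twist conformation",
                "adjacent stack quality", "non-adjacent stack quality",
                "upward", "downward", "inward", "outward",
                "cis orientation", "trans orientation")) {
    add_class(lab, "quality")
  }

  props <- list()
  add_prop <- function(label, inverse = NULL, transitive = FALSE,
                       symmetric = FALSE, parents = character(0)) {
    id <- schema_id(label)
    if (!is.null(props[[id]])) stop("duplicate schema label/id: ", label)
    props[[id]] <<- list(
      label = label,
      inverse = if (is.null(inverse)) NULL else schema_id(inverse),
      transitive = transitive, symmetric = symmetric,
      parents = vapply(parents, schema_id, ""))
    id
  }
  add_prop("has part", inverse = "part of", transitive = TRUE)
  add_prop("part of", inverse = "has part", transitive = TRUE)
  add_prop("has proper part", inverse = "proper part of",
           parents = "has part")
  add_prop("proper part of", inverse = "has proper part",
           parents = "part of")
  add_prop("externally connected to", symmetric = TRUE)
  add_prop("is about", inverse = "is subject of")
  add_prop("is subject of", inverse = "is about")
  add_prop("is represented by", inverse = "represents")
  add_prop("represents", inverse = "is represented by")
  add_prop("has quality", inverse = "quality of")
  add_prop("quality of", inverse = "has quality")
  add_prop("isImmediatelyBefore", inverse = "isImmediatelyAfter")
  add_prop("isImmediatelyAfter", inverse = "isImmediatelyBefore")

  ax <- data.frame(
    subclass = vapply(unname(AGGLOMERATE_LABEL), schema_id, ""),
    prop = schema_id("part of"),
    filler = vapply(unname(EDGE_CLASS_LABEL[names(AGGLOMERATE_LABEL)]),
                    schema_id, ""),
    stringsAsFactors = FALSE
  )

  labels <- c(vapply(cls, `[[`, "", "label"),
              vapply(props, `[[`, "", "label"))
  ids <- c(names(cls), names(props))
  if (anyDuplicated(labels)) {
    stop("duplicate label in schema: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  }
  label_to_id <- stats::setNames(ids, labels)

  cat <- structure(
    list(classes = cls, properties = props, existential_axioms = ax,
         label_to_id = label_to_id),
    class = "schema_catalog"
  )
  validate_schema(cat)
  cat
}

validate_schema <- function(cat) {
  for (pid in names(cat$properties)) {
    inv <- cat$properties[[pid]]$inverse
    if (!is.null(inv)) {
      stopifnot(identical(cat$properties[[inv]]$inverse, pid))
    }
  }
  # acyclicity of the class hierarchy
  for (cid in names(cat$classes)) {
    anc <- superclasses_of(cat, cid)
    stopifnot(cid %in% anc)  # reflexive closure includes itself, no cycle trap
  }
  invisible(cat)
}

#' @export
print.schema_catalog <- function(x, ...) {
  cat(sprintf("<schema catalog: %d classes, %d properties, %d existential axioms>\n",
              length(x$classes), length(x$properties),
              nrow(x$existential_axioms)))
  invisible(x)
}

#' Reflexive-transitive superclasses of a class
#'
#' Follows subclass parents and membership in agglomerating (union) classes
#' to a fixed point.
#'
#' @param schema A `schema_catalog`.
#' @param class_id Class id (use [resolve_label()] to map a label).
#' @return Character vector of class ids, including `class_id` itself.
#' @export
superclasses_of <- function(schema, class_id) {
  if (is.null(schema$classes[[class_id]])) {
    stop("unknown class id: ", class_id)
  }
  seen <- character(0)
  frontier <- class_id
  guard <- 0
  while (length(frontier)) {
    guard <- guard + 1
    if (guard > 10000) stop("cycle detected in class hierarchy")
    nxt <- character(0)
    for (cid in frontier) {
      if (cid %in% seen) next
      seen <- c(seen, cid)
      entry <- schema$classes[[cid]]
      nxt <- c(nxt, entry$parents)
      for (aid in names(schema$classes)) {
        eu <- schema$classes[[aid]]$equivalent_union
        if (!is.null(eu) && cid %in% eu) nxt <- c(nxt, aid)
      }
    }
    frontier <- setdiff(unique(nxt), seen)
  }
  sort(seen)
}

#' Resolve an rdfs:label to an entity id
#'
#' Exact, case-sensitive lookup over schema classes and properties, then
#' over the individuals registered in an optional knowledge graph.
#'
#' @param label The label text.
#' @param schema A `schema_catalog`.
#' @param graph Optional `kb_graph` whose `label_index` is consulted.
#' @return The entity id (class/property id or individual URI).
#' @export
resolve_label <- function(label, schema, graph = NULL) {
  hit <- schema$label_to_id[label]
  if (!is.na(hit)) return(unname(hit))
  if (!is.null(graph)) {
    hit <- graph$label_index[label]
    if (!is.na(hit)) return(unname(hit))
  }
  pool <- c(names(schema$label_to_id),
            if (!is.null(graph)) names(graph$label_index))
  near <- utils::head(pool[utils::adist(label, pool) <=
                             max(2, nchar(label) %/% 4)], 5)
  stop("unresolved label: '", label, "'",
       if (length(near)) paste0(" (near misses: ",
                                paste(sQuote(near), collapse = ", "), ")"))
}

#' One-line-per-entry dump of the schema catalog
#' @param schema A `schema_catalog`.
#' @return Character vector (invisibly); also printed.
#' @export
schema_dump <- function(schema) {
  out <- c(
    vapply(names(schema$classes), function(id) {
      e <- schema$classes[[id]]
      sprintf("class %-40s '%s'%s%s", id, e$label,
              if (length(e$parents)) paste0(" < ", paste(e$parents, collapse = ",")) else "",
              if (!is.null(e$equivalent_union))
                paste0(" = union(", paste(e$equivalent_union, collapse = ","), ")") else "")
    }, ""),
    vapply(names(schema$properties), function(id) {
      e <- schema$properties[[id]]
      sprintf("prop  %-40s '%s'%s%s%s", id, e$label,
              if (!is.null(e$inverse)) paste0(" inv=", e$inverse) else "",
              if (e$transitive) " transitive" else "",
              if (e$symmetric) " symmetric" else "")
    }, ""),
    apply(schema$existential_axioms, 1, function(row) {
      sprintf("axiom %s SubClassOf (%s some %s)", row["subclass"],
              row["prop"], row["filler"])
    })
  )
  cat(out, sep = "\n")
  invisible(out)
}
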