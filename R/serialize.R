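# Turtle and OWL 2 functional-syntax serialization of the mini ontology and of
# instance graphs.  The Turtle route round-trips: read_ontology_turtle()
# reconstructs an equal `ohd_ontology` from emit_ontology(g, "turtle").

ONTOLOGY_IRI <- "http://purl.example.org/ohd-mini"

#' Serialize the mini ontology
#'
#' @param g An `ohd_ontology`.
#' @param format `"turtle"` or `"owl_functional"`.
#' @return A single string with the serialization.
#' @export
#' @examples
#' cat(substr(emit_ontology(build_mini_ohd(), "turtle"), 1, 300))
emit_ontology <- function(g, format = c("turtle", "owl_functional")) {
  format <- match.arg(format)
  validate_ontology(g)
  if (format == "turtle") emit_ontology_turtle(g) else emit_ontology_ofn(g)
}

#' Write the mini ontology to a file
#'
#' @param g An `ohd_ontology`.
#' @param path Output path; extension does not matter.
#' @param format `"turtle"` or `"owl_functional"`.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(g, path, format = c("turtle", "owl_functional")) {
  writeLines(emit_ontology(g, format), path)
  invisible(path)
}

#' @noRd
emit_ontology_turtle <- function(g) {
  out <- c(
    ttl_prefix_block(),
    "",
    paste0("<", ONTOLOGY_IRI, "> a owl:Ontology ."),
    "",
    "ohd:definition a owl:AnnotationProperty ;",
    "    rdfs:label \"definition\" .",
    "ohd:term_source a owl:AnnotationProperty ;",
    "    rdfs:label \"term source\" .",
    ""
  )
  lit <- function(x) paste0("\"", ttl_escape(x), "\"")

  for (k in seq_len(nrow(g$terms))) {
    tm <- g$terms[k, ]
    lines <- c(
      paste0(tm$id, " a owl:Class ;"),
      paste0("    rdfs:label ", lit(tm$label), " ;"),
      if (nzchar(tm$definition)) paste0("    ohd:definition ", lit(tm$definition), " ;"),
      paste0("    ohd:term_source ", lit(tm$source), " ;"),
      if (length(tm$parents[[1]]))
        paste0("    rdfs:subClassOf ", paste(tm$parents[[1]], collapse = " , "), " ;")
    )
    lines[length(lines)] <- sub(" ;$", " .", lines[length(lines)])
    out <- c(out, lines, "")
  }

  for (k in seq_len(nrow(g$properties))) {
    p <- g$properties[k, ]
    types <- if (p$kind == "object") "owl:ObjectProperty" else "owl:DatatypeProperty"
    if (p$transitive) types <- paste(types, "owl:TransitiveProperty", sep = " , ")
    lines <- c(
      paste0(p$id, " a ", types, " ;"),
      paste0("    rdfs:label ", lit(p$label), " ;"),
      if (!is.na(p$super_property))
        paste0("    rdfs:subPropertyOf ", p$super_property, " ;")
    )
    lines[length(lines)] <- sub(" ;$", " .", lines[length(lines)])
    out <- c(out, lines, "")
  }

  some <- function(prop, filler) {
    paste0("[ a owl:Restriction ; owl:onProperty ", prop,
           " ; owl:someValuesFrom ", filler, " ]")
  }
  for (k in seq_len(nrow(g$axioms))) {
    a <- g$axioms[k, ]
    line <- switch(
      a$kind,
      existential_restriction = paste0(
        a$class, " rdfs:subClassOf ", some(a$property, a$filler), " ."),
      union_definition = paste0(
        a$class, " owl:equivalentClass [ a owl:Class ; owl:unionOf ( ",
        paste(a$operands[[1]], collapse = " "), " ) ] ."),
      negated_part = {
        ops <- a$operands[[1]]
        inner <- paste0(
          "[ a owl:Class ; owl:intersectionOf ( ", ops$dentition,
          " [ a owl:Class ; owl:complementOf ",
          some(ops$part_property, ops$tooth), " ] ) ]")
        paste0(a$class, " owl:equivalentClass [ a owl:Class ; owl:intersectionOf ( ",
               ops$parent, " ", some(a$property, inner), " ) ] .")
      },
      stop("unknown axiom kind: ", a$kind)
    )
    out <- c(out, line)
  }
  paste(out, collapse = "\n")
}

#' @noRd
emit_ontology_ofn <- function(g) {
  pf <- ohd_prefixes()
  out <- c(
    paste0("Prefix(", names(pf), ":=<", unname(pf), ">)"),
    "",
    paste0("Ontology(<", ONTOLOGY_IRI, ">")
  )
  lit <- function(x) paste0("\"", ttl_escape(x), "\"")
  for (k in seq_len(nrow(g$terms))) {
    tm <- g$terms[k, ]
    out <- c(out,
      paste0("Declaration(Class(", tm$id, "))"),
      paste0("AnnotationAssertion(rdfs:label ", tm$id, " ", lit(tm$label), ")"),
      if (nzchar(tm$definition))
        paste0("AnnotationAssertion(ohd:definition ", tm$id, " ", lit(tm$definition), ")"),
      if (length(tm$parents[[1]]))
        paste0("SubClassOf(", tm$id, " ", tm$parents[[1]], ")"))
  }
  for (k in seq_len(nrow(g$properties))) {
    p <- g$properties[k, ]
    decl <- if (p$kind == "object") "ObjectProperty" else "DataProperty"
    out <- c(out,
      paste0("Declaration(", decl, "(", p$id, "))"),
      paste0("AnnotationAssertion(rdfs:label ", p$id, " ", lit(p$label), ")"),
      if (p$transitive) paste0("TransitiveObjectProperty(", p$id, ")"),
      if (!is.na(p$super_property))
        paste0("SubObjectPropertyOf(", p$id, " ", p$super_property, ")"))
  }
  some <- function(prop, filler) paste0("ObjectSomeValuesFrom(", prop, " ", filler, ")")
  for (k in seq_len(nrow(g$axioms))) {
    a <- g$axioms[k, ]
    out <- c(out, switch(
      a$kind,
      existential_restriction =
        paste0("SubClassOf(", a$class, " ", some(a$property, a$filler), ")"),
      union_definition =
        paste0("EquivalentClasses(", a$class, " ObjectUnionOf(",
               paste(a$operands[[1]], collapse = " "), "))"),
      negated_part = {
        ops <- a$operands[[1]]
        inner <- paste0("ObjectIntersectionOf(", ops$dentition,
                        " ObjectComplementOf(", some(ops$part_property, ops$tooth), "))")
        paste0("EquivalentClasses(", a$class, " ObjectIntersectionOf(",
               ops$parent, " ", some(a$property, inner), "))")
      }))
  }
  paste(c(out, ")"), collapse = "\n")
}

# ---- reading the ontology back ----------------------------------------------

#' Read a mini-ontology Turtle serialization
#'
#' Parses Turtle produced by [emit_ontology()] (or an equivalent subset) and
#' reconstructs the `ohd_ontology` object: named classes with labels,
#' definitions, source tags and parents; object/data properties with
#' transitivity flags and super-properties; and the existential, union and
#' negated-parthood axioms.
#'
#' @param x A file path or a single Turtle string.
#' @return An `ohd_ontology`.
#' @export
read_ontology_turtle <- function(x) {
  text <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else paste(x, collapse = "\n")
  parsed <- ttl_parse(text)
  tr <- parsed$triples
  tr$subject <- iri_to_curie(tr$subject)
  tr$predicate <- iri_to_curie(tr$predicate)
  tr$object <- ifelse(tr$obj_kind == "iri", iri_to_curie(tr$object), tr$object)

  pv <- function(s, p) tr$object[tr$subject == s & tr$predicate == p]
  node_props <- function(b) tr[tr$subject == b, , drop = FALSE]
  list_items <- function(head) {
    items <- character(0)
    while (!identical(head, "rdf:nil")) {
      items <- c(items, pv(head, "rdf:first"))
      head <- pv(head, "rdf:rest")
    }
    items
  }

  type_of <- tr[tr$predicate == "rdf:type", ]
  class_ids <- type_of$subject[type_of$object == "owl:Class" &
                                 !startsWith(type_of$subject, "_:")]
  ann_ids <- type_of$subject[type_of$object == "owl:AnnotationProperty"]
  class_ids <- setdiff(class_ids, ann_ids)

  terms <- list(); axioms <- list()
  for (id in class_ids) {
    lab <- pv(id, "rdfs:label"); def <- pv(id, "ohd:definition")
    src <- pv(id, "ohd:term_source")
    sup <- pv(id, "rdfs:subClassOf")
    named_sup <- sup[!startsWith(sup, "_:")]
    terms[[length(terms) + 1L]] <- new_term(
      id, if (length(lab)) lab[1] else "",
      if (length(def)) def[1] else "",
      named_sup, if (length(src)) src[1] else "OHD")
    # restriction superclasses -> existential axioms
    for (b in sup[startsWith(sup, "_:")]) {
      axioms[[length(axioms) + 1L]] <- new_axiom(
        "existential_restriction", id,
        pv(b, "owl:onProperty"), pv(b, "owl:someValuesFrom"))
    }
    for (b in pv(id, "owl:equivalentClass")) {
      uni <- pv(b, "owl:unionOf")
      inter <- pv(b, "owl:intersectionOf")
      if (length(uni)) {
        axioms[[length(axioms) + 1L]] <- new_axiom(
          "union_definition", id, operands = list(list_items(uni)))
      } else if (length(inter)) {
        items <- list_items(inter)
        parent <- items[!startsWith(items, "_:")][1]
        restr <- items[startsWith(items, "_:")][1]
        about_prop <- pv(restr, "owl:onProperty")
        filler <- pv(restr, "owl:someValuesFrom")
        filler_items <- list_items(pv(filler, "owl:intersectionOf"))
        dentition <- filler_items[!startsWith(filler_items, "_:")][1]
        compl_node <- filler_items[startsWith(filler_items, "_:")][1]
        neg_restr <- pv(compl_node, "owl:complementOf")
        axioms[[length(axioms) + 1L]] <- new_axiom(
          "negated_part", id, about_prop,
          operands = list(list(parent = parent, dentition = dentition,
                               part_property = pv(neg_restr, "owl:onProperty"),
                               tooth = pv(neg_restr, "owl:someValuesFrom"))))
      }
    }
  }

  props <- list()
  for (id in unique(type_of$subject[type_of$object %in%
                                    c("owl:ObjectProperty", "owl:DatatypeProperty")])) {
    kinds <- pv(id, "rdf:type")
    lab <- pv(id, "rdfs:label"); sup <- pv(id, "rdfs:subPropertyOf")
    props[[length(props) + 1L]] <- new_property(
      id, if (length(lab)) lab[1] else "",
      if ("owl:ObjectProperty" %in% kinds) "object" else "data",
      transitive = "owl:TransitiveProperty" %in% kinds,
      super_property = if (length(sup)) sup[1] else NA_character_)
  }

  structure(list(terms = dplyr::bind_rows(terms),
                 properties = dplyr::bind_rows(props),
                 axioms = dplyr::bind_rows(axioms)),
            class = "ohd_ontology")
}

# ---- instance graphs --------------------------------------------------------

#' Create an empty instance-graph assertion table
#'
#' Instance graphs are tibbles of subject-predicate-object assertions with an
#' object kind (`"iri"` or `"literal"`) and an optional literal datatype.
#'
#' @return A zero-row assertion tibble.
#' @export
empty_instance_graph <- function() {
  tibble::tibble(subject = character(0), predicate = character(0),
                 object = character(0), obj_kind = character(0),
                 datatype = character(0))
}

#' Serialize an instance graph
#'
#' @param assertions An assertion tibble (see [empty_instance_graph()]).
#' @param format `"turtle"` or `"owl_functional"`.
#' @return A single string.  The Turtle output imports the mini ontology.
#' @export
emit_instances <- function(assertions, format = c("turtle", "owl_functional")) {
  format <- match.arg(format)
  if (format == "turtle") {
    body <- if (nrow(assertions)) {
      df <- assertions |>
        dplyr::mutate(rendered = paste(.data$predicate,
                                       ttl_term(.data$object, .data$obj_kind, .data$datatype))) |>
        dplyr::group_by(.data$subject) |>
        dplyr::summarise(block = paste0(
          .data$subject[1], " ", paste(.data$rendered, collapse = " ;\n    "), " ."),
          .groups = "drop")
      df$block
    } else character(0)
    paste(c(ttl_prefix_block(),
            "",
            paste0("<", ONTOLOGY_IRI, "/data> a owl:Ontology ; owl:imports <",
                   ONTOLOGY_IRI, "> ."),
            "",
            body), collapse = "\n")
  } else {
    pf <- ohd_prefixes()
    lines <- c(paste0("Prefix(", names(pf), ":=<", unname(pf), ">)"), "",
               paste0("Ontology(<", ONTOLOGY_IRI, "/data>"))
    if (nrow(assertions)) {
      inds <- unique(assertions$subject)
      lines <- c(lines, paste0("Declaration(NamedIndividual(", inds, "))"))
      a <- assertions
      rendered <- ifelse(
        a$predicate == "rdf:type",
        paste0("ClassAssertion(", a$object, " ", a$subject, ")"),
        ifelse(a$obj_kind == "literal",
               paste0("DataPropertyAssertion(", a$predicate, " ", a$subject, " ",
                      ttl_term(a$object, a$obj_kind, a$datatype), ")"),
               paste0("ObjectPropertyAssertion(", a$predicate, " ", a$subject,
                      " ", a$object, ")")))
      lines <- c(lines, rendered)
    }
    paste(c(lines, ")"), collapse = "\n")
  }
}

#' Write an instance graph to a file
#' @param assertions An assertion tibble.
#' @param path Output path.
#' @param format `"turtle"` or `"owl_functional"`.
#' @return `path`, invisibly.
#' @export
write_instances <- function(assertions, path, format = c("turtle", "owl_functional")) {
  writeLines(emit_instances(assertions, format), path)
  invisible(path)
}

#' Read an instance graph from Turtle
#'
#' @param x A file path or a single Turtle string.
#' @return An assertion tibble with CURIE-compacted resources; the ontology
#'   header triples are dropped.
#' @export
read_instances_turtle <- function(x) {
  text <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else paste(x, collapse = "\n")
  tr <- ttl_parse(text)$triples
  tr$subject <- iri_to_curie(tr$subject)
  tr$predicate <- iri_to_curie(tr$predicate)
  tr$object <- ifelse(tr$obj_kind == "iri", iri_to_curie(tr$object), tr$object)
  tr$datatype <- ifelse(is.na(tr$datatype), NA_character_, iri_to_curie(tr$datatype))
  hdr <- tr$subject == paste0("<", ONTOLOGY_IRI, "/data>") |
    tr$subject == paste0(ONTOLOGY_IRI, "/data") |
    tr$predicate == "owl:imports" |
    (tr$predicate == "rdf:type" & tr$object == "owl:Ontology")
  tr[!hdr, c("subject", "predicate", "object", "obj_kind", "datatype")]
}
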