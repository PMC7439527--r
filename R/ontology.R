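#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# ---- term / property / axiom constructors -----------------------------------

new_term <- function(id, label, definition, parents, source) {
  tibble::tibble(id = id, label = label, definition = definition,
                 parents = list(parents), source = source)
}

new_property <- function(id, label, kind, transitive = FALSE,
                         super_property = NA_character_) {
  tibble::tibble(id = id, label = label, kind = kind,
                 transitive = transitive, super_property = super_property)
}

# Axioms are one-row tibbles.  Kinds:
#   existential_restriction: class `subClassOf` (property some filler)
#   union_definition:        class `equivalentTo` union(operands)
#   negated_part:            class `equivalentTo`
#                            parent and (is_about some (dentition and
#                                        not has_part some tooth))
new_axiom <- function(kind, class, property = NA_character_,
                      filler = NA_character_, operands = list(NULL)) {
  tibble::tibble(kind = kind, class = class, property = property,
                 filler = filler, operands = operands)
}

# ---- tooth naming -----------------------------------------------------------

# Universal Tooth Numbering System, permanent dentition: 1 = right upper third
# molar, 16 = left upper third molar, 17 = left lower third molar, 32 = right
# lower third molar.  Labels follow anatomical naming ("Right upper third
# secondary molar tooth") so alternate coding systems can map onto the class.
#' @noRd
tooth_anatomical_label <- function(n) {
  stopifnot(all(n >= 1L & n <= 32L))
  jaw <- ifelse(n <= 16L, "upper", "lower")
  side <- ifelse(n <= 8L | n >= 25L, "Right", "Left")
  pos <- ifelse(n <= 16L, ifelse(n <= 8L, n, 17L - n),
                ifelse(n <= 24L, n - 16L, 33L - n))
  type <- c("third secondary molar", "second secondary molar",
            "first secondary molar", "second secondary premolar",
            "first secondary premolar", "secondary canine",
            "lateral secondary incisor", "central secondary incisor")[pos]
  paste(side, jaw, type, "tooth")
}

#' Tooth surface letter codes
#'
#' Bijective map between the one-letter surface codes used in dental charting
#' and the surface-enamel classes of the mini ontology: M mesial, O occlusal,
#' D distal, B buccal, F facial, L lingual, I incisal.
#'
#' @return A tibble with columns `letter`, `surface` (short name) and `class`
#'   (ontology class CURIE).
#' @export
#' @examples
#' surface_codes()
surface_codes <- function() {
  tibble::tibble(
    letter = c("M", "O", "D", "B", "F", "L", "I"),
    surface = c("mesial", "occlusal", "distal", "buccal",
                "facial", "lingual", "incisal"),
    class = paste0("ohd:", .data$surface, "_surface_enamel")
  )
}

# CDT billing codes known to the pipeline, with the most specific procedure
# class each maps to and whether the coded procedure is tooth- and
# surface-specific.
#' CDT code table used by the generator and translator
#'
#' @return A tibble with columns `code`, `class` (procedure class CURIE),
#'   `tooth_specific`, `surface_specific` and a short `description`.
#' @export
cdt_code_table <- function() {
  tibble::tribble(
    ~code,    ~class,                            ~tooth_specific, ~surface_specific, ~description,
    "D0120",  "ohd:oral_evaluation",             FALSE, FALSE, "periodic oral evaluation",
    "D2140",  "ohd:amalgam_filling_restoration", TRUE,  TRUE,  "amalgam, one surface",
    "D2150",  "ohd:amalgam_filling_restoration", TRUE,  TRUE,  "amalgam, two surfaces",
    "D2160",  "ohd:amalgam_filling_restoration", TRUE,  TRUE,  "amalgam, three surfaces",
    "D2161",  "ohd:amalgam_filling_restoration", TRUE,  TRUE,  "amalgam, four or more surfaces",
    "D2330",  "ohd:resin_filling_restoration",   TRUE,  TRUE,  "resin-based composite, one surface, anterior",
    "D2331",  "ohd:resin_filling_restoration",   TRUE,  TRUE,  "resin-based composite, two surfaces, anterior",
    "D2332",  "ohd:resin_filling_restoration",   TRUE,  TRUE,  "resin-based composite, three surfaces, anterior",
    "D2335",  "ohd:resin_filling_restoration",   TRUE,  TRUE,  "resin-based composite, four or more surfaces, anterior",
    "D2392",  "ohd:resin_filling_restoration",   TRUE,  TRUE,  "resin-based composite, two surfaces, posterior",
    "D2740",  "ohd:crown_restoration_procedure", TRUE,  FALSE, "crown, porcelain/ceramic",
    "D3310",  "ohd:endodontic_procedure",        TRUE,  FALSE, "endodontic therapy, anterior tooth",
    "D7140",  "ohd:tooth_extraction_procedure",  TRUE,  FALSE, "extraction, erupted tooth"
  )
}

# ---- missing tooth finding --------------------------------------------------

#' Equivalence axiom for a missing-tooth finding
#'
#' Builds the negated-parthood definition for "missing tooth N finding": the
#' finding is a missing tooth finding that is about a secondary dentition
#' lacking tooth N as a part.  Realist ontologies cannot assert findings about
#' non-existent teeth, so the finding is about the dentition instead, and the
#' absence is expressed by negating `has part`.
#'
#' @param tooth_number Integer in 1..32 (Universal Tooth Numbering System).
#' @return A one-row axiom tibble of kind `negated_part`.
#' @export
#' @examples
#' define_missing_tooth_finding(5)
define_missing_tooth_finding <- function(tooth_number) {
  if (length(tooth_number) != 1L || is.na(tooth_number) ||
      tooth_number != as.integer(tooth_number) ||
      tooth_number < 1L || tooth_number > 32L) {
    stop("tooth_number must be a single integer between 1 and 32")
  }
  n <- as.integer(tooth_number)
  new_axiom(
    kind = "negated_part",
    class = sprintf("ohd:missing_tooth_%d_finding", n),
    property = "ohd:is_about",
    operands = list(list(
      parent = "ohd:missing_tooth_finding",
      dentition = "ohd:secondary_dentition",
      part_property = "ohd:has_part",
      tooth = sprintf("ohd:tooth_%d", n)
    ))
  )
}

# ---- the mini ontology ------------------------------------------------------

#' Build the miniature oral-health ontology
#'
#' Constructs the class/property/axiom subset this pipeline needs: the
#' health-care-encounter hierarchy down to specific restoration procedures,
#' patient/provider/gender roles and their bearers, teeth 1-32 with the seven
#' surface-enamel classes, restoration materials, dental findings (including
#' the negated-parthood missing-tooth definitions for every tooth), and CDT
#' billing-code classes for every code the generator emits.  `is part of`,
#' `has part` and `subsequent_encounter` are flagged transitive;
#' `next_encounter` is a subproperty of `subsequent_encounter`.
#'
#' IRIs are minted under a single project namespace with label-derived CURIE
#' suffixes; the `source` field records which community ontology a borrowed
#' term specializes, without reusing that ontology's identifiers.
#'
#' @return An object of class `ohd_ontology`: a list of tibbles `terms`,
#'   `properties` and `axioms`.
#' @export
#' @examples
#' ont <- build_mini_ohd()
#' ont
build_mini_ohd <- function() {
  t <- list()
  add <- function(id, label, definition, parents, source) {
    t[[length(t) + 1L]] <<- new_term(id, label, definition, parents, source)
  }

  # upper level
  add("ohd:entity", "entity", "Root of the mini ontology.", character(0), "BFO")
  add("ohd:continuant", "continuant",
      "An entity that persists through time while maintaining its identity.",
      "ohd:entity", "BFO")
  add("ohd:occurrent", "occurrent",
      "An entity that unfolds itself in time, such as a process.",
      "ohd:entity", "BFO")
  add("ohd:material_entity", "material entity",
      "A continuant that has some portion of matter as part.",
      "ohd:continuant", "BFO")
  add("ohd:specifically_dependent_continuant", "specifically dependent continuant",
      "A continuant that depends on some independent bearer.",
      "ohd:continuant", "BFO")
  add("ohd:realizable_entity", "realizable entity",
      "A dependent continuant whose instances can be realized in processes.",
      "ohd:specifically_dependent_continuant", "BFO")
  add("ohd:role", "role",
      "A realizable entity an independent continuant can gain or lose without physical change.",
      "ohd:realizable_entity", "BFO")
  add("ohd:generically_dependent_continuant", "generically dependent continuant",
      "A continuant that can migrate between bearers, such as information.",
      "ohd:continuant", "BFO")
  add("ohd:information_content_entity", "information content entity",
      "A generically dependent continuant that is about something.",
      "ohd:generically_dependent_continuant", "IAO")
  add("ohd:process", "process",
      "An occurrent that has temporal parts and a participant.",
      "ohd:occurrent", "BFO")

  # people and organisms
  add("ohd:human_being", "human being", "A member of the species Homo sapiens.",
      "ohd:material_entity", "OGMS")
  add("ohd:human_dental_patient", "human dental patient",
      "A human being who bears a dental patient role.",
      "ohd:human_being", "OHD")
  add("ohd:dental_health_care_provider", "dental health care provider",
      "A human being who bears a dental health care provider role.",
      "ohd:human_being", "OHD")
  add("ohd:female_organism", "female organism",
      "A gonochoristic organism that can produce female gametes.",
      "ohd:human_being", "CARO")
  add("ohd:male_organism", "male organism",
      "A gonochoristic organism that can produce male gametes.",
      "ohd:human_being", "CARO")

  # oral anatomy
  add("ohd:mouth", "mouth", "The oral cavity of an organism.",
      "ohd:material_entity", "FMA")
  add("ohd:secondary_dentition", "secondary dentition",
      "The set of permanent teeth of an organism.", "ohd:material_entity", "FMA")
  add("ohd:tooth", "tooth", "A hard, calcified structure in the jaws used for mastication.",
      "ohd:material_entity", "FMA")
  add("ohd:natural_tooth", "natural tooth",
      "A tooth that has not been restored and is not a prosthesis.",
      "ohd:tooth", "OHD")
  add("ohd:restored_tooth", "restored tooth",
      "A tooth part of which has been replaced by dental restoration material.",
      "ohd:tooth", "OHD")
  add("ohd:prosthetic_tooth", "prosthetic tooth",
      "An artificial replacement of a whole tooth, such as a pontic or implant.",
      "ohd:material_entity", "OHD")
  add("ohd:functional_tooth", "functional tooth",
      "A natural, restored, or prosthetic tooth; defined as their union so instances are classified by the reasoner.",
      "ohd:material_entity", "OHD")
  for (n in 1:32) {
    add(sprintf("ohd:tooth_%d", n), tooth_anatomical_label(n),
        sprintf("Permanent tooth number %d in the Universal Tooth Numbering System.", n),
        "ohd:tooth", "FMA")
  }
  add("ohd:surface_enamel_of_tooth", "surface enamel of tooth",
      "A portion of enamel constituting part of a tooth's anatomical crown, into which restoration material is placed.",
      "ohd:material_entity", "OHD")
  sc <- surface_codes()
  for (k in seq_len(nrow(sc))) {
    add(sc$class[k], paste(sc$surface[k], "surface enamel of tooth"),
        sprintf("The %s portion of the surface enamel of a tooth (charting letter '%s').",
                sc$surface[k], sc$letter[k]),
        "ohd:surface_enamel_of_tooth", "OHD")
  }

  # restoration materials
  add("ohd:processed_material", "processed material",
      "A material entity created or changed during material processing.",
      "ohd:material_entity", "OBI")
  add("ohd:dental_restoration_material", "dental restoration material",
      "A processed material that bears a dental restoration material role.",
      "ohd:processed_material", "OHD")
  add("ohd:metal_dental_restoration_material", "metal dental restoration material",
      "A dental restoration material that consists mostly of metal atoms.",
      "ohd:dental_restoration_material", "OHD")
  add("ohd:amalgam_dental_restoration_material", "amalgam dental restoration material",
      "A metal restoration material composed of a mercury alloy.",
      "ohd:metal_dental_restoration_material", "OHD")
  add("ohd:resin_dental_restoration_material", "resin dental restoration material",
      "A tooth-colored restoration material made from resin, silica and other components.",
      "ohd:dental_restoration_material", "OHD")

  # roles
  add("ohd:patient_role", "patient role",
      "A role realized by the process of being under the care of a health care provider.",
      "ohd:role", "OGMS")
  add("ohd:dental_patient_role", "dental patient role",
      "A patient role realized by being under the care of a dental health care provider.",
      "ohd:patient_role", "OHD")
  add("ohd:health_care_provider_role", "health care provider role",
      "A role that inheres in a person licensed to provide health care.",
      "ohd:role", "OGMS")
  add("ohd:dental_health_care_provider_role", "dental health care provider role",
      "A health care provider role realized in a dental health care process.",
      "ohd:health_care_provider_role", "OHD")
  add("ohd:gender_role", "gender role",
      "A human social role realized in behavior considered socially appropriate for a specific sex in a culture.",
      "ohd:role", "OMRSE")
  add("ohd:female_gender_role", "female gender role",
      "A gender role associated with the female sex in the culture in question.",
      "ohd:gender_role", "OMRSE")
  add("ohd:male_gender_role", "male gender role",
      "A gender role associated with the male sex in the culture in question.",
      "ohd:gender_role", "OMRSE")
  add("ohd:prosthetic_role", "prosthetic role",
      "A role borne by a material entity that replaces a missing body part.",
      "ohd:role", "OHD")
  add("ohd:functional_prosthetic_role", "functional prosthetic role",
      "A prosthetic role whose bearer performs the function of the replaced body part.",
      "ohd:prosthetic_role", "OHD")
  add("ohd:dental_restoration_material_role", "dental restoration material role",
      "A functional prosthetic role borne by a portion of dental restoration material and realized in a tooth restoration procedure.",
      "ohd:functional_prosthetic_role", "OHD")
  add("ohd:tooth_to_undergo_endodontic_procedure_role",
      "tooth to undergo endodontic procedure role",
      "A role borne by a tooth and realized in an endodontic procedure.",
      "ohd:role", "OHD")

  # encounters and procedures
  add("ohd:health_care_encounter", "health care encounter",
      "A temporally connected health care process realizing a provider role and a patient role.",
      "ohd:process", "OGMS")
  add("ohd:dental_visit", "dental visit",
      "A health care encounter during which dental procedures are performed; procedures are parts of their visit.",
      "ohd:health_care_encounter", "OHD")
  add("ohd:dental_procedure", "dental procedure",
      "A health care encounter that realizes a dental patient role in a diagnostic or therapeutic process.",
      "ohd:health_care_encounter", "OHD")
  add("ohd:oral_evaluation", "oral evaluation",
      "A dental procedure in which a patient's oral health is examined.",
      "ohd:dental_procedure", "OHD")
  add("ohd:endodontic_procedure", "endodontic procedure",
      "A dental procedure performed on the pulp chamber and/or root canal of a tooth.",
      "ohd:dental_procedure", "OHD")
  add("ohd:surgical_dental_procedure", "surgical dental procedure",
      "A dental procedure involving structural alteration of soft tissue or bone in or around the oral cavity.",
      "ohd:dental_procedure", "OHD")
  add("ohd:tooth_extraction_procedure", "tooth extraction procedure",
      "A surgical dental procedure that removes a tooth from the oral cavity.",
      "ohd:surgical_dental_procedure", "OHD")
  add("ohd:tooth_restoration_procedure", "tooth restoration procedure",
      "A dental procedure in which a tooth or part of a tooth is replaced by dental restoration material.",
      "ohd:dental_procedure", "OHD")
  add("ohd:crown_restoration_procedure", "crown restoration procedure",
      "A tooth restoration procedure in which an artificial crown replaces all or part of the natural crown.",
      "ohd:tooth_restoration_procedure", "OHD")
  add("ohd:direct_restoration_procedure", "direct restoration procedure",
      "A tooth restoration procedure in which material is placed via direct insertion.",
      "ohd:tooth_restoration_procedure", "OHD")
  add("ohd:indirect_restoration_procedure", "indirect restoration procedure",
      "A tooth restoration procedure in which material is placed via an attachment process.",
      "ohd:tooth_restoration_procedure", "OHD")
  add("ohd:intracoronal_restoration_procedure", "intracoronal restoration procedure",
      "A tooth restoration procedure in which material is placed into a site in the crown of the tooth.",
      "ohd:tooth_restoration_procedure", "OHD")
  add("ohd:veneer_restoration_procedure", "veneer restoration procedure",
      "A tooth restoration procedure in which a thin layer of material is placed over one or more surfaces.",
      "ohd:tooth_restoration_procedure", "OHD")
  add("ohd:amalgam_filling_restoration", "amalgam filling restoration",
      "An intracoronal restoration procedure that uses amalgam to restore the tooth.",
      c("ohd:intracoronal_restoration_procedure", "ohd:direct_restoration_procedure"),
      "OHD")
  add("ohd:resin_filling_restoration", "resin filling restoration",
      "An intracoronal restoration procedure that uses resin to restore the tooth.",
      c("ohd:intracoronal_restoration_procedure", "ohd:direct_restoration_procedure"),
      "OHD")
  add("ohd:inlay_restoration_procedure", "inlay restoration procedure",
      "An intracoronal restoration procedure in which a pre-formed filling is cemented into the tooth.",
      c("ohd:intracoronal_restoration_procedure", "ohd:indirect_restoration_procedure"),
      "OHD")

  # findings
  add("ohd:clinical_finding", "clinical finding",
      "A representation that is an output of a clinical history taking, examination or imaging.",
      "ohd:information_content_entity", "OGMS")
  add("ohd:dental_finding", "dental finding",
      "A clinical finding output by a dental exam, about the oral cavity or its parts.",
      "ohd:clinical_finding", "OHD")
  add("ohd:caries_finding", "caries finding",
      "A dental finding that indicates a carious lesion of a tooth.",
      "ohd:dental_finding", "OHD")
  add("ohd:missing_tooth_finding", "missing tooth finding",
      "A dental finding, about a patient's mouth, that some tooth is missing.",
      "ohd:dental_finding", "OHD")
  for (n in 1:32) {
    add(sprintf("ohd:missing_tooth_%d_finding", n),
        sprintf("missing tooth %d finding", n),
        sprintf("A missing tooth finding in which tooth %d is found to be missing.", n),
        "ohd:missing_tooth_finding", "OHD")
  }

  # billing codes
  add("ohd:centrally_registered_identifier", "centrally registered identifier",
      "A symbol registered as part of some organization's registry.",
      "ohd:information_content_entity", "IAO")
  add("ohd:current_dental_terminology_code", "current dental terminology code",
      "A centrally registered identifier maintained by the American Dental Association for recording dental services.",
      "ohd:centrally_registered_identifier", "OHD")
  cdt <- cdt_code_table()
  for (k in seq_len(nrow(cdt))) {
    add(paste0("ohd:CDT_", cdt$code[k]),
        paste("current dental terminology code", cdt$code[k]),
        sprintf("CDT code %s: %s.", cdt$code[k], cdt$description[k]),
        "ohd:current_dental_terminology_code", "CDT")
  }

  terms <- dplyr::bind_rows(t)

  properties <- dplyr::bind_rows(
    new_property("ohd:is_part_of", "is part of", "object", transitive = TRUE),
    new_property("ohd:has_part", "has part", "object", transitive = TRUE),
    new_property("ohd:has_participant", "has participant", "object"),
    new_property("ohd:realizes", "realizes", "object"),
    new_property("ohd:inheres_in", "inheres in", "object"),
    new_property("ohd:is_about", "is about", "object"),
    new_property("ohd:has_specified_input", "has specified input", "object"),
    new_property("ohd:is_dental_restoration_of", "is dental restoration of", "object"),
    new_property("ohd:subsequent_encounter", "subsequent encounter", "object",
                 transitive = TRUE),
    new_property("ohd:next_encounter", "next encounter", "object",
                 super_property = "ohd:subsequent_encounter"),
    new_property("ohd:occurrence_date", "occurrence date", "data"),
    new_property("ohd:birth_date", "birth date", "data")
  )

  ax <- list(
    new_axiom("existential_restriction", "ohd:amalgam_filling_restoration",
              "ohd:has_specified_input", "ohd:amalgam_dental_restoration_material"),
    new_axiom("existential_restriction", "ohd:resin_filling_restoration",
              "ohd:has_specified_input", "ohd:resin_dental_restoration_material"),
    new_axiom("existential_restriction", "ohd:tooth_restoration_procedure",
              "ohd:realizes", "ohd:dental_restoration_material_role"),
    new_axiom("union_definition", "ohd:functional_tooth",
              operands = list(c("ohd:natural_tooth", "ohd:restored_tooth",
                                "ohd:prosthetic_tooth")))
  )
  # CDT codes are information artifacts about procedure types
  for (k in seq_len(nrow(cdt))) {
    ax[[length(ax) + 1L]] <- new_axiom(
      "existential_restriction", paste0("ohd:CDT_", cdt$code[k]),
      "ohd:is_about", cdt$class[k])
  }
  for (n in 1:32) ax[[length(ax) + 1L]] <- define_missing_tooth_finding(n)

  g <- structure(
    list(terms = terms, properties = properties, axioms = dplyr::bind_rows(ax)),
    class = "ohd_ontology"
  )
  validate_ontology(g)
  g
}

# ---- validation and helpers -------------------------------------------------

#' Validate an `ohd_ontology` object
#'
#' Checks the structural invariants: unique ids, a single root, non-empty
#' labels, an acyclic subclass graph, resolvable axiom operands, data
#' properties never transitive, and the negated-parthood axioms referencing
#' exactly one dentition class and one tooth class.
#'
#' @param g An `ohd_ontology`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_ontology <- function(g) {
  stopifnot(inherits(g, "ohd_ontology"))
  terms <- g$terms
  if (anyDuplicated(terms$id)) stop("duplicate term ids")
  if (anyDuplicated(g$properties$id)) stop("duplicate property ids")
  if (any(!nzchar(terms$label))) stop("term with empty label")
  n_root <- sum(lengths(terms$parents) == 0L)
  if (n_root != 1L) stop("ontology must have exactly one root term, found ", n_root)
  all_parents <- unique(unlist(terms$parents))
  unknown <- setdiff(all_parents, terms$id)
  if (length(unknown)) stop("unresolved parent(s): ", paste(unknown, collapse = ", "))
  if (any(!nzchar(terms$definition[terms$source == "OHD"]))) {
    stop("every OHD-new term must carry a definition")
  }
  # acyclicity via ancestor computation (errors on cycle)
  invisible(subclass_ancestors(g))

  p <- g$properties
  if (any(p$transitive & p$kind == "data")) stop("data properties cannot be transitive")
  sup_ok <- is.na(p$super_property) | p$super_property %in% p$id
  if (!all(sup_ok)) stop("unresolved super_property")
  for (k in which(!is.na(p$super_property))) {
    if (p$kind[match(p$super_property[k], p$id)] != p$kind[k]) {
      stop("super_property kind mismatch for ", p$id[k])
    }
  }

  a <- g$axioms
  known <- c(terms$id, p$id)
  for (k in seq_len(nrow(a))) {
    refs <- c(a$class[k], a$property[k], a$filler[k])
    ops <- a$operands[[k]]
    if (a$kind[k] == "negated_part") {
      stopifnot(is.list(ops))
      if (!identical(sum(ops$dentition %in% terms$id), 1L) ||
          !grepl("^ohd:tooth_\\d+$", ops$tooth)) {
        stop("negated_part axiom must reference one dentition and one tooth class")
      }
      refs <- c(refs, ops$parent, ops$dentition, ops$part_property, ops$tooth)
    } else if (!is.null(ops)) {
      refs <- c(refs, unlist(ops))
    }
    refs <- refs[!is.na(refs)]
    bad <- setdiff(refs, known)
    if (length(bad)) stop("axiom operand(s) do not resolve: ", paste(bad, collapse = ", "))
  }
  invisible(g)
}

# Named list mapping each term id to the ids of all its ancestors (reflexive
# closure excluded).  Errors if the subclass graph has a cycle.
#' @noRd
subclass_ancestors <- function(g) {
  ids <- g$terms$id
  parents <- stats::setNames(g$terms$parents, ids)
  memo <- new.env(parent = emptyenv())
  in_progress <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    if (!is.null(in_progress[[id]])) stop("subclass cycle involving ", id)
    in_progress[[id]] <- TRUE
    ps <- parents[[id]]
    out <- unique(c(ps, unlist(lapply(ps, anc))))
    rm(list = id, envir = in_progress)
    memo[[id]] <- out
    out
  }
  stats::setNames(lapply(ids, anc), ids)
}

# Tibble (class, descendant) over the reflexive-transitive subclass closure.
#' @noRd
subclass_descendants_table <- function(g) {
  anc <- subclass_ancestors(g)
  up <- tibble::tibble(
    descendant = rep(names(anc), lengths(anc)),
    class = unlist(anc, use.names = FALSE)
  )
  dplyr::bind_rows(up, tibble::tibble(descendant = g$terms$id, class = g$terms$id))
}

#' Descendant classes of a class (reflexive)
#'
#' @param g An `ohd_ontology`.
#' @param class A class CURIE.
#' @return Character vector of `class` and all its subclasses.
#' @export
subclass_descendants <- function(g, class) {
  if (!class %in% g$terms$id) stop("unknown class: ", class)
  tab <- subclass_descendants_table(g)
  tab$descendant[tab$class == class]
}

#' @export
print.ohd_ontology <- function(x, ...) {
  cat("<ohd_ontology> ", nrow(x$terms), " classes, ",
      nrow(x$properties), " properties, ", nrow(x$axioms), " axioms\n", sep = "")
  src <- sort(table(x$terms$source), decreasing = TRUE)
  cat("  term sources: ",
      paste(names(src), src, sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Order-insensitive equality on terms, properties and axioms.
#' @noRd
ontology_equal <- function(a, b) {
  norm_terms <- function(g) {
    g$terms |>
      dplyr::mutate(parents = lapply(.data$parents, sort)) |>
      dplyr::arrange(.data$id)
  }
  norm_ax <- function(g) {
    g$axioms |>
      dplyr::mutate(opkey = vapply(.data$operands, function(o)
        paste(unlist(o), collapse = "|"), "")) |>
      dplyr::arrange(.data$kind, .data$class, .data$property, .data$filler, .data$opkey)
  }
  isTRUE(all.equal(norm_terms(a), norm_terms(b))) &&
    isTRUE(all.equal(dplyr::arrange(a$properties, .data$id),
                     dplyr::arrange(b$properties, .data$id))) &&
    isTRUE(all.equal(norm_ax(a), norm_ax(b)))
}
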