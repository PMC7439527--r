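# In-memory semantic store over the mini ontology.  Materializes exactly the
# entailments the clinical queries need: subclass-closure instance typing
# (evaluated at query time against the ontology's descendant table),
# transitive closure for properties flagged transitive, union-class
# membership (functional tooth), propagated occurrence dates, and the
# per-patient next_encounter chain with its transitive subsequent_encounter
# closure.  Base assertions are never mutated; every inferred assertion is
# reproducible from the base.

#' Load instance graphs and materialize entailments
#'
#' @param ontology An `ohd_ontology`.
#' @param instances An `ohd_instance_graph`, an assertion tibble, a path to a
#'   Turtle file, or a list mixing these; all are unioned.
#' @return An object of class `ohd_store` with the base assertions, the
#'   inferred assertion set, and query caches.  Occurrence dates are not yet
#'   propagated and the encounter chain not yet built; see
#'   [propagate_occurrence_dates()] and [build_encounter_chain()], or
#'   [materialize_pipeline()] for the full sequence.
#' @export
load_and_materialize <- function(ontology, instances) {
  stopifnot(inherits(ontology, "ohd_ontology"))
  as_assertions <- function(x) {
    if (inherits(x, "ohd_instance_graph")) return(x$assertions)
    if (is.character(x)) return(read_instances_turtle(x))
    stopifnot(is.data.frame(x))
    x
  }
  if (inherits(instances, "ohd_instance_graph") || is.data.frame(instances) ||
      is.character(instances)) {
    instances <- list(instances)
  }
  base <- dplyr::distinct(dplyr::bind_rows(lapply(instances, as_assertions)))
  if (nrow(base) == 0L) base <- empty_instance_graph()

  desc_tab <- subclass_descendants_table(ontology)
  types <- base |>
    dplyr::filter(.data$predicate == "rdf:type") |>
    dplyr::transmute(ind = .data$subject, class = .data$object) |>
    dplyr::distinct()

  # union-class membership: an instance of any operand is an instance of the
  # defined union class
  union_ax <- ontology$axioms[ontology$axioms$kind == "union_definition", ]
  union_types <- list()
  for (k in seq_len(nrow(union_ax))) {
    members <- unique(unlist(lapply(union_ax$operands[[k]], function(op)
      desc_tab$descendant[desc_tab$class == op])))
    inds <- unique(types$ind[types$class %in% members])
    if (length(inds)) {
      union_types[[k]] <- tibble::tibble(ind = inds, class = union_ax$class[k])
    }
  }
  union_types <- dplyr::bind_rows(union_types)
  all_types <- dplyr::distinct(dplyr::bind_rows(types, union_types))

  # transitive closure for transitive-flagged properties present in the data
  trans_props <- ontology$properties$id[ontology$properties$transitive]
  closure <- list()
  for (p in intersect(trans_props, unique(base$predicate))) {
    edges <- base |>
      dplyr::filter(.data$predicate == p) |>
      dplyr::select(from = "subject", to = "object")
    clo <- transitive_closure(edges)
    extra <- dplyr::anti_join(clo, edges, by = c("from", "to"))
    if (nrow(extra)) {
      closure[[p]] <- tibble::tibble(
        subject = extra$from, predicate = p, object = extra$to,
        obj_kind = "iri", datatype = NA_character_)
    }
  }

  parts <- unname(closure)
  if (nrow(union_types)) {
    parts <- c(parts, list(tibble::tibble(
      subject = union_types$ind, predicate = "rdf:type",
      object = union_types$class, obj_kind = "iri", datatype = NA_character_)))
  }
  inferred <- if (length(parts)) dplyr::bind_rows(parts) else empty_instance_graph()

  dates <- base |>
    dplyr::filter(.data$predicate == "ohd:occurrence_date") |>
    dplyr::transmute(ind = .data$subject, date = as.Date(.data$object)) |>
    dplyr::distinct()

  structure(list(ontology = ontology, base = base, inferred = inferred,
                 types = all_types, desc_tab = desc_tab, dates = dates,
                 chain = NULL),
            class = "ohd_store")
}

# iterative join until fixpoint; input/output tibble(from, to)
#' @noRd
transitive_closure <- function(edges) {
  clo <- dplyr::distinct(edges)
  repeat {
    new <- clo |>
      dplyr::inner_join(clo, by = c("to" = "from"), relationship = "many-to-many") |>
      dplyr::transmute(from = .data$from, to = .data$to.y) |>
      dplyr::distinct() |>
      dplyr::anti_join(clo, by = c("from", "to"))
    if (nrow(new) == 0L) break
    clo <- dplyr::bind_rows(clo, new)
  }
  clo
}

#' All assertions of a store (base plus inferred)
#' @param store An `ohd_store`.
#' @return An assertion tibble.
#' @export
store_assertions <- function(store) {
  dplyr::bind_rows(store$base, store$inferred)
}

#' Instances of a class, respecting the subclass hierarchy
#'
#' An individual asserted to be of a subclass is returned when querying for
#' any of its superclasses; union-defined classes (functional tooth) include
#' the instances of their operands.
#'
#' @param store An `ohd_store`.
#' @param class A class CURIE present in the ontology.
#' @return Character vector of distinct individual IRIs.
#' @export
instances_of <- function(store, class) {
  desc <- subclass_descendants(store$ontology, class)
  unique(store$types$ind[store$types$class %in% desc])
}

#' @export
print.ohd_store <- function(x, ...) {
  cat("<ohd_store> ", nrow(x$base), " base + ", nrow(x$inferred),
      " inferred assertions; chain ",
      if (is.null(x$chain)) "not built" else
        paste0("built (", nrow(x$chain), " next_encounter edges)"),
      "\n", sep = "")
  invisible(x)
}

#' Propagate occurrence dates from wholes to their parts
#'
#' Processes that are parts of dated processes (restorations within a dated
#' visit, and deeper nestings) inherit the date of their whole, to any depth.
#' The pass is idempotent; a process reachable from wholes carrying different
#' dates, or already dated differently from its whole, raises an error
#' reporting the conflicting individuals.
#'
#' @param store An `ohd_store`.
#' @return The store with propagated dates added to its inferred assertions.
#' @export
propagate_occurrence_dates <- function(store) {
  stopifnot(inherits(store, "ohd_store"))
  part_edges <- store$base |>
    dplyr::filter(.data$predicate == "ohd:is_part_of") |>
    dplyr::select(part = "subject", whole = "object")
  dates <- store$dates
  repeat {
    inherited <- part_edges |>
      dplyr::inner_join(dates, by = c("whole" = "ind"),
                        relationship = "many-to-many") |>
      dplyr::distinct(ind = .data$part, .data$date)
    conflicts <- inherited |>
      dplyr::bind_rows(dates |> dplyr::semi_join(inherited, by = "ind")) |>
      dplyr::distinct() |>
      dplyr::count(.data$ind) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(conflicts)) {
      stop("conflicting occurrence dates for: ",
           paste(utils::head(conflicts$ind, 10), collapse = ", "))
    }
    new <- dplyr::anti_join(inherited, dates, by = "ind")
    if (nrow(new) == 0L) break
    dates <- dplyr::bind_rows(dates, new)
  }
  added <- dplyr::anti_join(dates, store$dates, by = "ind")
  store$dates <- dates
  if (nrow(added)) {
    store$inferred <- dplyr::bind_rows(
      store$inferred,
      tibble::tibble(subject = added$ind, predicate = "ohd:occurrence_date",
                     object = format(added$date, "%Y-%m-%d"),
                     obj_kind = "literal", datatype = "xsd:date")) |>
      dplyr::distinct()
  }
  store
}

# encounters with their patient and date; undated encounters excluded
#' @noRd
encounter_table <- function(store, warn = TRUE) {
  encs <- instances_of(store, "ohd:health_care_encounter")
  patients <- instances_of(store, "ohd:human_dental_patient")
  pat_link <- store$base |>
    dplyr::filter(.data$predicate == "ohd:has_participant",
                  .data$subject %in% encs, .data$object %in% patients) |>
    dplyr::distinct(enc = .data$subject, patient = .data$object)
  tab <- pat_link |> dplyr::inner_join(store$dates, by = c("enc" = "ind"))
  undated <- setdiff(pat_link$enc, tab$enc)
  if (warn && length(undated)) {
    warning(length(undated), " undated encounter(s) excluded from the chain")
  }
  tab
}

#' Build the per-patient encounter chain
#'
#' For each patient, links every encounter to the encounter(s) at that
#' patient's next distinct date: `e1 next_encounter e2` holds iff
#' `date(e2) > date(e1)` and no encounter of the patient falls strictly
#' between.  Several encounters can share a day (a visit and its procedures),
#' so one encounter may have several next encounters; same-day encounters are
#' never linked to each other.  `subsequent_encounter`, the transitive
#' superproperty, is available through [subsequent_encounters()].
#'
#' @param store An `ohd_store` with dates propagated.
#' @return The store with `chain` filled and next_encounter edges added to
#'   the inferred assertions.
#' @export
build_encounter_chain <- function(store) {
  stopifnot(inherits(store, "ohd_store"))
  enc <- encounter_table(store)
  if (nrow(enc) == 0L) {
    store$chain <- tibble::tibble(from = character(0), to = character(0))
    return(store)
  }
  enc <- enc |>
    dplyr::group_by(.data$patient) |>
    dplyr::mutate(rank = dplyr::dense_rank(.data$date)) |>
    dplyr::ungroup()
  nxt <- enc |>
    dplyr::mutate(rank = .data$rank - 1L) |>
    dplyr::inner_join(enc, by = c("patient", "rank"),
                      relationship = "many-to-many",
                      suffix = c("_to", "_from")) |>
    dplyr::distinct(from = .data$enc_from, to = .data$enc_to)
  store$chain <- nxt
  if (nrow(nxt)) {
    store$inferred <- dplyr::bind_rows(
      store$inferred,
      tibble::tibble(subject = nxt$from, predicate = "ohd:next_encounter",
                     object = nxt$to, obj_kind = "iri",
                     datatype = NA_character_)) |>
      dplyr::distinct()
  }
  store
}

#' Transitive subsequent_encounter pairs
#'
#' The closure of `next_encounter`: every ordered pair of a patient's
#' encounters on strictly increasing dates.  Computed lazily from encounter
#' dates, which provably equals the transitive closure of the chain edges.
#'
#' @param store An `ohd_store` with the chain built.
#' @return A tibble with columns `from` and `to`.
#' @export
subsequent_encounters <- function(store) {
  enc <- encounter_table(store, warn = FALSE)
  enc |>
    dplyr::inner_join(enc, by = "patient", suffix = c("_from", "_to"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$date_to > .data$date_from) |>
    dplyr::distinct(from = .data$enc_from, to = .data$enc_to)
}

#' Count procedure instances of a class
#'
#' Counts distinct instances of the class or any of its subclasses, the
#' hierarchical-query pattern that replaces enumerating billing codes.
#'
#' @param store An `ohd_store`.
#' @param class A procedure class CURIE.
#' @return Integer count.
#' @export
count_procedures_by_type <- function(store, class) {
  length(instances_of(store, class))
}

#' Breakdown of procedures using a material
#'
#' Finds the procedures whose specified input is a material of the given
#' class (or a subclass) and tabulates them by the procedure's asserted, most
#' specific class label, in descending count order.
#'
#' @param store An `ohd_store`.
#' @param material_class A material class CURIE, e.g.
#'   `"ohd:resin_dental_restoration_material"`.
#' @return A tibble with columns `procedure_name` and `total`.
#' @export
breakdown_by_material <- function(store, material_class) {
  mats <- instances_of(store, material_class)
  procs <- store$base |>
    dplyr::filter(.data$predicate == "ohd:has_specified_input",
                  .data$object %in% mats) |>
    dplyr::distinct(proc = .data$subject)
  labels <- stats::setNames(store$ontology$terms$label, store$ontology$terms$id)
  procs |>
    dplyr::inner_join(store$types, by = c("proc" = "ind"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$class %in% names(labels)) |>
    dplyr::semi_join(
      store$base |> dplyr::filter(.data$predicate == "rdf:type") |>
        dplyr::transmute(proc = .data$subject, class = .data$object),
      by = c("proc", "class")) |>
    dplyr::count(procedure_name = unname(labels[.data$class]), name = "total") |>
    dplyr::arrange(dplyr::desc(.data$total))
}

# per-procedure context needed by cohort extraction, all derived from the
# graph: asserted class, patient, date, tooth number, restored surfaces
#' @noRd
procedure_context <- function(store) {
  procs <- instances_of(store, "ohd:dental_procedure")
  asserted <- store$base |>
    dplyr::filter(.data$predicate == "rdf:type", .data$subject %in% procs) |>
    dplyr::distinct(proc = .data$subject, class = .data$object)
  patients <- instances_of(store, "ohd:human_dental_patient")
  part <- store$base |> dplyr::filter(.data$predicate == "ohd:has_participant")
  pat <- part |>
    dplyr::filter(.data$object %in% patients) |>
    dplyr::distinct(proc = .data$subject, patient = .data$object)
  tooth_types <- store$types |>
    dplyr::filter(grepl("^ohd:tooth_\\d+$", .data$class)) |>
    dplyr::mutate(tooth = as.integer(sub("^ohd:tooth_", "", .data$class))) |>
    dplyr::distinct(.data$ind, .data$tooth)
  tooth <- part |>
    dplyr::inner_join(tooth_types, by = c("object" = "ind")) |>
    dplyr::distinct(proc = .data$subject, .data$tooth)
  # surfaces: proc -> material -> is_dental_restoration_of -> surface type
  sc <- surface_codes()
  surf_types <- store$types |>
    dplyr::filter(.data$class %in% sc$class) |>
    dplyr::mutate(letter = sc$letter[match(.data$class, sc$class)]) |>
    dplyr::distinct(.data$ind, .data$letter)
  mat_of <- store$base |>
    dplyr::filter(.data$predicate == "ohd:has_specified_input") |>
    dplyr::distinct(proc = .data$subject, mat = .data$object)
  restored <- store$base |>
    dplyr::filter(.data$predicate == "ohd:is_dental_restoration_of") |>
    dplyr::distinct(mat = .data$subject, surface = .data$object)
  surfaces <- mat_of |>
    dplyr::inner_join(restored, by = "mat", relationship = "many-to-many") |>
    dplyr::inner_join(surf_types, by = c("surface" = "ind")) |>
    dplyr::group_by(.data$proc) |>
    dplyr::summarise(surfaces = paste(
      SURFACE_ORDER[SURFACE_ORDER %in% .data$letter], collapse = ""),
      .groups = "drop")
  asserted |>
    dplyr::left_join(pat, by = "proc") |>
    dplyr::left_join(store$dates, by = c("proc" = "ind")) |>
    dplyr::left_join(tooth, by = "proc") |>
    dplyr::left_join(surfaces, by = "proc")
}

#' Extract the restoration-failure cohort
#'
#' For every instance of the requested restoration class, finds the earliest
#' strictly later event that counts as a failure: another restoration or
#' inlay on the same tooth sharing at least one initially restored surface, a
#' crown on the same tooth, an endodontic procedure on the same tooth, or an
#' extraction of the same tooth.  Restorations with no qualifying later event
#' are censored at the patient's last recorded encounter; restorations with
#' no later encounter at all are excluded.  When several failure kinds share
#' the earliest date the kind label follows the priority extraction >
#' endodontic > crown > refill (the time to event is unaffected).
#'
#' @param store An `ohd_store` with dates propagated and the chain built.
#' @param restoration_class Cohort-defining class CURIE (default resin
#'   fillings).
#' @return A tibble of first-event records: `restoration`, `patient`,
#'   `restoration_date`, `restoration_class`, `tooth`, `surfaces`, `outcome`
#'   (`"failed"`/`"censored"`), `outcome_date`, `failure_kind`.
#' @export
extract_restoration_cohort <- function(store,
                                       restoration_class = "ohd:resin_filling_restoration") {
  ctx <- procedure_context(store)
  desc <- function(cls) subclass_descendants(store$ontology, cls)

  cohort <- ctx |> dplyr::filter(.data$class %in% desc(restoration_class))
  incomplete <- is.na(cohort$tooth) | is.na(cohort$surfaces) |
    !nzchar(dplyr::coalesce(cohort$surfaces, "")) | is.na(cohort$date) |
    is.na(cohort$patient)
  if (any(incomplete)) {
    warning(sum(incomplete), " restoration(s) lacking tooth/surfaces/date skipped")
    cohort <- cohort[!incomplete, , drop = FALSE]
  }

  ev <- ctx |>
    dplyr::mutate(kind = dplyr::case_when(
      .data$class %in% desc("ohd:tooth_extraction_procedure") ~ "extraction",
      .data$class %in% desc("ohd:endodontic_procedure") ~ "endodontic",
      .data$class %in% desc("ohd:crown_restoration_procedure") ~ "crown",
      .data$class %in% desc("ohd:intracoronal_restoration_procedure") ~ "refill",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$kind), !is.na(.data$tooth), !is.na(.data$date),
                  !is.na(.data$patient))
  ev <- ev[ev$kind != "refill" |
             (!is.na(ev$surfaces) & nzchar(ev$surfaces)), , drop = FALSE]

  prio <- c(extraction = 1L, endodontic = 2L, crown = 3L, refill = 4L)
  cand <- cohort |>
    dplyr::inner_join(
      ev |> dplyr::select(patient = "patient", tooth = "tooth",
                          ev_proc = "proc", ev_date = "date",
                          ev_kind = "kind", ev_surfaces = "surfaces"),
      by = c("patient", "tooth"), relationship = "many-to-many") |>
    dplyr::filter(.data$ev_date > .data$date)
  if (nrow(cand)) {
    shared <- function(a, b) {
      any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
    }
    keep <- cand$ev_kind != "refill" |
      mapply(shared, cand$surfaces, cand$ev_surfaces, USE.NAMES = FALSE)
    cand <- cand[keep, , drop = FALSE]
  }
  first_fail <- cand |>
    dplyr::mutate(prio = prio[.data$ev_kind]) |>
    dplyr::arrange(.data$proc, .data$ev_date, .data$prio) |>
    dplyr::distinct(.data$proc, .keep_all = TRUE) |>
    dplyr::select(proc = "proc", outcome_date = "ev_date", failure_kind = "ev_kind")

  enc <- encounter_table(store, warn = FALSE)
  last_enc <- enc |>
    dplyr::group_by(.data$patient) |>
    dplyr::summarise(last_date = max(.data$date), .groups = "drop")

  cohort |>
    dplyr::left_join(first_fail, by = "proc") |>
    dplyr::left_join(last_enc, by = "patient") |>
    dplyr::filter(!is.na(.data$outcome_date) | .data$last_date > .data$date) |>
    dplyr::transmute(
      restoration = .data$proc, patient = .data$patient,
      restoration_date = .data$date, restoration_class = .data$class,
      tooth = .data$tooth, surfaces = .data$surfaces,
      outcome = ifelse(is.na(.data$outcome_date), "censored", "failed"),
      outcome_date = dplyr::coalesce(.data$outcome_date, .data$last_date),
      failure_kind = .data$failure_kind) |>
    dplyr::arrange(.data$patient, .data$restoration_date, .data$restoration)
}

#' Patient demographics from the graph
#'
#' @param store An `ohd_store`.
#' @return A tibble with `patient` (IRI), `birth_date` and `gender`, derived
#'   from birth-date literals and the gender-role individuals inhering in
#'   each patient.
#' @export
patient_demographics <- function(store) {
  patients <- instances_of(store, "ohd:human_dental_patient")
  births <- store$base |>
    dplyr::filter(.data$predicate == "ohd:birth_date",
                  .data$subject %in% patients) |>
    dplyr::distinct(patient = .data$subject, birth_date = as.Date(.data$object))
  gr <- store$types |>
    dplyr::filter(.data$class %in% c("ohd:female_gender_role", "ohd:male_gender_role")) |>
    dplyr::mutate(gender = ifelse(.data$class == "ohd:female_gender_role",
                                  "female", "male"))
  inheres <- store$base |>
    dplyr::filter(.data$predicate == "ohd:inheres_in") |>
    dplyr::select(ind = "subject", patient = "object")
  genders <- gr |>
    dplyr::inner_join(inheres, by = "ind") |>
    dplyr::distinct(.data$patient, .data$gender)
  tibble::tibble(patient = patients) |>
    dplyr::left_join(births, by = "patient") |>
    dplyr::left_join(genders, by = "patient")
}

#' Run translation and full materialization in one call
#'
#' Convenience wrapper: translate the practice rows, load them with the
#' ontology, propagate occurrence dates and build the encounter chain.
#'
#' @param x An `ohd_practice` or patient_history rows tibble.
#' @param ontology An `ohd_ontology` (defaults to [build_mini_ohd()]).
#' @return A fully materialized `ohd_store`.
#' @export
materialize_pipeline <- function(x, ontology = build_mini_ohd()) {
  g <- translate_practice(x)
  store <- load_and_materialize(ontology, g)
  store <- propagate_occurrence_dates(store)
  build_encounter_chain(store)
}

#' Shipped SPARQL queries
#'
#' Returns the text of one of the SPARQL 1.1 queries distributed with the
#' package (runnable against the exported Turtle with any SPARQL engine;
#' subclass reasoning is expressed with `rdfs:subClassOf*` property paths).
#'
#' @param name Query name; with no argument, lists available names.
#' @return Query text (single string), or a character vector of names.
#' @export
ohd_sparql <- function(name = NULL) {
  dir <- system.file("extdata", "sparql", package = "ohdsurv")
  files <- list.files(dir, pattern = "\\.rq$")
  names <- sub("\\.rq$", "", files)
  if (is.null(name)) return(names)
  if (!name %in% names) {
    stop("unknown query '", name, "'; available: ", paste(names, collapse = ", "))
  }
  paste(readLines(file.path(dir, paste0(name, ".rq")), warn = FALSE),
        collapse = "\n")
}

#' Export a materialized store as Turtle
#'
#' Writes the ontology followed by the base and inferred instance assertions,
#' so external SPARQL engines can query without reasoning support.
#'
#' @param store An `ohd_store`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_store_turtle <- function(store, path) {
  txt <- paste(emit_ontology(store$ontology, "turtle"),
               emit_instances(store_assertions(store), "turtle"),
               sep = "\n\n")
  writeLines(txt, path)
  invisible(path)
}
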