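# shared fixtures: small configs and hand-built patient_history rows

small_config <- function(n_patients = 40, seed = 1, ...) {
  generator_config(n_patients = n_patients, seed = seed, ...)
}

# a patient_history tibble from compact arguments
ph_rows <- function(...) {
  rows <- tibble::tribble(...)
  defaults <- tibble::tibble(
    patient_id = "P1", provider_id = "prov01",
    birth_date = as.Date("1960-06-15"), gender = "female",
    encounter_date = as.Date("2000-01-01"), ada_code = "D0120",
    tooth = NA_integer_, surfaces = NA_character_, row_kind = "evaluation")
  for (col in names(defaults)) {
    if (!col %in% names(rows)) rows[[col]] <- defaults[[col]]
  }
  rows$encounter_date <- as.Date(rows$encounter_date)
  rows$birth_date <- as.Date(rows$birth_date)
  rows$tooth <- as.integer(rows$tooth)
  rows[, names(defaults)]
}

# hand-built dated-encounter instance fragments for chain tests
enc_graph <- function(encs) {
  # encs: tibble(enc, patient, date, class)
  dplyr::bind_rows(
    tibble::tibble(subject = unique(encs$patient), predicate = "rdf:type",
                   object = "ohd:human_dental_patient", obj_kind = "iri",
                   datatype = NA_character_),
    tibble::tibble(subject = encs$enc, predicate = "rdf:type",
                   object = encs$class, obj_kind = "iri",
                   datatype = NA_character_),
    tibble::tibble(subject = encs$enc, predicate = "ohd:has_participant",
                   object = encs$patient, obj_kind = "iri",
                   datatype = NA_character_),
    tibble::tibble(subject = encs$enc, predicate = "ohd:occurrence_date",
                   object = format(as.Date(encs$date), "%Y-%m-%d"),
                   obj_kind = "literal", datatype = "xsd:date"))
}
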