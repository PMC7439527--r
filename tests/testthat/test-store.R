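ont <- build_mini_ohd()

test_that("instance queries respect the subclass closure", {
  a <- dplyr::bind_rows(
    tibble::tibble(subject = "ex:p1", predicate = "rdf:type",
                   object = "ohd:resin_filling_restoration",
                   obj_kind = "iri", datatype = NA_character_))
  store <- load_and_materialize(ont, a)
  expect_identical(instances_of(store, "ohd:dental_procedure"), "ex:p1")
  expect_identical(instances_of(store, "ohd:intracoronal_restoration_procedure"), "ex:p1")
  expect_identical(instances_of(store, "ohd:health_care_encounter"), "ex:p1")
  expect_length(instances_of(store, "ohd:crown_restoration_procedure"), 0L)
})

test_that("transitive parthood is materialized: surface to patient", {
  a <- tibble::tibble(
    subject = c("ex:s", "ex:t", "ex:pat", "ex:s", "ex:t"),
    predicate = c("rdf:type", "rdf:type", "rdf:type",
                  "ohd:is_part_of", "ohd:is_part_of"),
    object = c("ohd:occlusal_surface_enamel", "ohd:tooth_3",
               "ohd:human_dental_patient", "ex:t", "ex:pat"),
    obj_kind = "iri", datatype = NA_character_)
  store <- load_and_materialize(ont, a)
  inferred <- store$inferred
  expect_true(any(inferred$subject == "ex:s" &
                    inferred$predicate == "ohd:is_part_of" &
                    inferred$object == "ex:pat"))
  # base is untouched and the inferred set is reproducible
  expect_identical(store$base, dplyr::distinct(a))
  store2 <- load_and_materialize(ont, a)
  expect_identical(store$inferred, store2$inferred)
})

test_that("union classification types natural/restored/prosthetic teeth as functional", {
  a <- tibble::tibble(
    subject = c("ex:t1", "ex:t2", "ex:t3"),
    predicate = "rdf:type",
    object = c("ohd:natural_tooth", "ohd:prosthetic_tooth", "ohd:tooth_5"),
    obj_kind = "iri", datatype = NA_character_)
  store <- load_and_materialize(ont, a)
  fn <- instances_of(store, "ohd:functional_tooth")
  expect_setequal(fn, c("ex:t1", "ex:t2"))  # a bare tooth_5 is not classified
})

test_that("empty instance data yields a store with the ontology only", {
  store <- load_and_materialize(ont, empty_instance_graph())
  expect_identical(nrow(store$base), 0L)
  expect_identical(nrow(store$inferred), 0L)
  expect_length(instances_of(store, "ohd:dental_procedure"), 0L)
})

test_that("occurrence dates propagate through nested parts and stay idempotent", {
  mk <- function(extra = NULL) {
    a <- dplyr::bind_rows(
      tibble::tibble(subject = "ex:v", predicate = "rdf:type",
                     object = "ohd:dental_visit", obj_kind = "iri",
                     datatype = NA_character_),
      tibble::tibble(subject = "ex:v", predicate = "ohd:occurrence_date",
                     object = "2003-05-02", obj_kind = "literal",
                     datatype = "xsd:date"),
      tibble::tibble(subject = c("ex:proc", "ex:sub"), predicate = "rdf:type",
                     object = c("ohd:tooth_restoration_procedure",
                                "ohd:dental_procedure"),
                     obj_kind = "iri", datatype = NA_character_),
      tibble::tibble(subject = c("ex:proc", "ex:sub"),
                     predicate = "ohd:is_part_of",
                     object = c("ex:v", "ex:proc"),
                     obj_kind = "iri", datatype = NA_character_),
      extra)
    load_and_materialize(ont, a)
  }
  store <- propagate_occurrence_dates(mk())
  d <- store$dates
  expect_identical(d$date[d$ind == "ex:proc"], as.Date("2003-05-02"))
  # three-level nesting: the innermost process is also dated
  expect_identical(d$date[d$ind == "ex:sub"], as.Date("2003-05-02"))

  # idempotent: re-running adds nothing
  again <- propagate_occurrence_dates(store)
  expect_identical(again$dates, store$dates)
  expect_identical(again$inferred, store$inferred)

  # already-dated part with the same date passes unchanged
  same <- mk(tibble::tibble(subject = "ex:proc",
                            predicate = "ohd:occurrence_date",
                            object = "2003-05-02", obj_kind = "literal",
                            datatype = "xsd:date"))
  expect_silent(propagate_occurrence_dates(same))

  # conflicting date errors
  conflict <- mk(tibble::tibble(subject = "ex:proc",
                                predicate = "ohd:occurrence_date",
                                object = "2004-01-01", obj_kind = "literal",
                                datatype = "xsd:date"))
  expect_error(propagate_occurrence_dates(conflict), "conflicting occurrence dates")
})

test_that("the encounter chain links strictly consecutive dates only", {
  encs <- tibble::tibble(
    enc = c("ex:e1", "ex:e2", "ex:e3"),
    patient = "ex:pat",
    date = as.Date(c("2000-01-01", "2001-06-01", "2003-01-01")),
    class = "ohd:dental_visit")
  store <- build_encounter_chain(load_and_materialize(ont, enc_graph(encs)))
  expect_identical(nrow(store$chain), 2L)
  expect_setequal(paste(store$chain$from, store$chain$to),
                  c("ex:e1 ex:e2", "ex:e2 ex:e3"))
  subs <- subsequent_encounters(store)
  expect_identical(nrow(subs), 3L)

  # one encounter: no links at all
  one <- tibble::tibble(enc = "ex:e1", patient = "ex:pat",
                        date = as.Date("2000-01-01"), class = "ohd:dental_visit")
  store1 <- build_encounter_chain(load_and_materialize(ont, enc_graph(one)))
  expect_identical(nrow(store1$chain), 0L)
})

test_that("same-day encounters share next links but are never linked to each other", {
  encs <- tibble::tibble(
    enc = c("ex:a1", "ex:a2", "ex:b"),
    patient = "ex:pat",
    date = as.Date(c("2000-01-01", "2000-01-01", "2000-06-01")),
    class = "ohd:dental_visit")
  store <- build_encounter_chain(load_and_materialize(ont, enc_graph(encs)))
  expect_setequal(paste(store$chain$from, store$chain$to),
                  c("ex:a1 ex:b", "ex:a2 ex:b"))
})

test_that("chain and closure equal the sort-and-link oracle on random fixtures", {
  for (seed in c(41, 42, 43)) {
    pr <- generate_practice(small_config(n_patients = 25, seed = seed))
    store <- materialize_pipeline(pr)
    enc <- ohdsurv:::encounter_table(store, warn = FALSE)
    oracle <- oracle_chain(enc)
    got_next <- dplyr::arrange(store$chain, from, to)
    expect_equal(as.data.frame(got_next), as.data.frame(oracle$next_edges))
    got_subs <- dplyr::arrange(subsequent_encounters(store), from, to)
    expect_equal(as.data.frame(got_subs), as.data.frame(oracle$subsequent))
    # transitive closure of next_encounter equals the lazy subsequent set
    clo <- ohdsurv:::transitive_closure(store$chain)
    expect_equal(as.data.frame(dplyr::arrange(clo, from, to)),
                 as.data.frame(oracle$subsequent))
  }
})

test_that("procedure counts use the hierarchy and match a brute-force closure count", {
  rows <- ph_rows(
    ~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind, ~encounter_date,
    "P1", "D2140", 3L, "O", "restoration", "2000-01-01",
    "P1", "D2150", 4L, "MO", "restoration", "2000-02-01",
    "P1", "D2160", 5L, "MOD", "restoration", "2000-03-01",
    "P2", "D2330", 8L, "M", "restoration", "2000-04-01",
    "P2", "D2392", 19L, "OD", "restoration", "2000-05-01")
  store <- materialize_pipeline(rows)
  expect_identical(count_procedures_by_type(store, "ohd:tooth_restoration_procedure"), 5L)
  expect_identical(count_procedures_by_type(store, "ohd:amalgam_filling_restoration"), 3L)
  expect_identical(count_procedures_by_type(store, "ohd:crown_restoration_procedure"), 0L)
  expect_error(count_procedures_by_type(store, "ohd:not_a_class"), "unknown class")

  # independent closure count: explicit descendant walk over the term table
  g <- store$ontology
  walk <- function(cls) {
    kids <- g$terms$id[vapply(g$terms$parents, function(p) cls %in% p, TRUE)]
    unique(c(cls, unlist(lapply(kids, walk))))
  }
  types <- store$base[store$base$predicate == "rdf:type", ]
  brute <- length(unique(types$subject[types$object %in%
                                         walk("ohd:dental_procedure")]))
  expect_identical(count_procedures_by_type(store, "ohd:dental_procedure"), brute)
})

test_that("material breakdown groups by most specific class in descending order", {
  pr <- generate_practice(small_config(n_patients = 40, seed = 12))
  store <- materialize_pipeline(pr)
  bd <- breakdown_by_material(store, "ohd:resin_dental_restoration_material")
  # oracle directly over the input rows: resin fillings only
  n_resin <- sum(pr$rows$ada_code %in% ORACLE_RESIN_CODES)
  expect_identical(bd$total[bd$procedure_name == "resin filling restoration"],
                   n_resin)
  expect_true(all(diff(bd$total) <= 0))
  none <- breakdown_by_material(store, "ohd:metal_dental_restoration_material")
  amalgam_codes <- c("D2140", "D2150", "D2160", "D2161")
  n_amalgam <- sum(pr$rows$ada_code %in% amalgam_codes)
  expect_identical(sum(none$total), n_amalgam)
})

test_that("cohort extraction applies the failure rules to hand fixtures", {
  # shared-surface refill on the same tooth -> failed at that date
  rows <- ph_rows(
    ~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind, ~encounter_date,
    "P1", "D2332", 19L, "MOD", "restoration", "2001-03-01",
    "P1", "D2330", 19L, "O", "refill", "2004-06-01")
  co <- extract_restoration_cohort(materialize_pipeline(rows))
  rec <- co[co$restoration_date == as.Date("2001-03-01"), ]
  expect_identical(rec$outcome, "failed")
  expect_identical(rec$outcome_date, as.Date("2004-06-01"))
  expect_identical(rec$failure_kind, "refill")

  # extraction of a different tooth does not fail the restoration
  rows2 <- ph_rows(
    ~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind, ~encounter_date,
    "P1", "D2332", 19L, "MOD", "restoration", "2001-03-01",
    "P1", "D7140", 12L, NA, "extraction", "2005-01-01",
    "P1", "D0120", NA, NA, "evaluation", "2006-02-02")
  co2 <- extract_restoration_cohort(materialize_pipeline(rows2))
  expect_identical(co2$outcome, "censored")
  expect_identical(co2$outcome_date, as.Date("2006-02-02"))
  expect_true(is.na(co2$failure_kind))

  # disjoint-surface refill on the same tooth censors too
  rows3 <- ph_rows(
    ~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind, ~encounter_date,
    "P1", "D2331", 19L, "MO", "restoration", "2001-03-01",
    "P1", "D2330", 19L, "B", "refill", "2004-06-01")
  co3 <- extract_restoration_cohort(materialize_pipeline(rows3))
  rec3 <- co3[co3$restoration_date == as.Date("2001-03-01"), ]
  expect_identical(rec3$outcome, "censored")

  # a restoration at the patient's last encounter is excluded entirely
  rows4 <- ph_rows(
    ~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind, ~encounter_date,
    "P1", "D0120", NA, NA, "evaluation", "2001-01-01",
    "P1", "D2330", 8L, "M", "restoration", "2002-03-01")
  co4 <- extract_restoration_cohort(materialize_pipeline(rows4))
  expect_identical(nrow(co4), 0L)
})

test_that("the minimal-date rule picks the earliest event, ties by severity", {
  rows <- ph_rows(
    ~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind, ~encounter_date,
    "P1", "D2332", 19L, "MOD", "restoration", "2001-03-01",
    "P1", "D3310", 19L, NA, "endodontic", "2003-01-01",
    "P1", "D2740", 19L, NA, "crown", "2003-01-01",
    "P1", "D7140", 19L, NA, "extraction", "2005-01-01")
  co <- extract_restoration_cohort(materialize_pipeline(rows))
  rec <- co[co$restoration_date == as.Date("2001-03-01"), ]
  expect_identical(rec$outcome_date, as.Date("2003-01-01"))
  expect_identical(rec$failure_kind, "endodontic")  # beats crown on the same day
})

test_that("graph-based extraction equals the relational oracle on generated fixtures", {
  pr <- generate_practice(small_config(n_patients = 50, seed = 77))
  store <- materialize_pipeline(pr)
  got <- cohort_as_oracle(extract_restoration_cohort(store))
  want <- oracle_cohort(pr$rows)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("materialization is monotone: adding data never removes inferences", {
  pr <- generate_practice(small_config(n_patients = 10, seed = 2))
  half <- pr$rows[seq_len(nrow(pr$rows) %/% 2), ]
  g_half <- translate_practice(half)
  g_full <- translate_practice(pr$rows)
  s_half <- load_and_materialize(ont, g_half)
  s_full <- load_and_materialize(ont, g_full)
  missing <- dplyr::anti_join(
    s_half$inferred, s_full$inferred,
    by = c("subject", "predicate", "object"))
  expect_identical(nrow(missing), 0L)
})
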