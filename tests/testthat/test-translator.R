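test_that("surface strings parse to ordered, duplicate-free surface codes", {
  expect_identical(parse_surface_field("MOD")$surface,
                   c("mesial", "occlusal", "distal"))
  expect_identical(nrow(parse_surface_field("")), 0L)
  expect_identical(parse_surface_field("MMO")$letter, c("M", "O"))
  expect_error(parse_surface_field("MXD"), "'X'")
})

test_that("tooth character arrays decode to 1-based positions", {
  expect_identical(decode_tooth_char_array("NNNNNYNNNNNNNNNNNNNNNNNNNNNNNNNN"), 6L)
  expect_identical(decode_tooth_char_array(strrep("N", 32)), integer(0))
  expect_identical(decode_tooth_char_array(strrep("Y", 32)), 1:32)
  expect_error(decode_tooth_char_array(strrep("N", 31)), "32 characters")
  expect_error(decode_tooth_char_array(paste0(strrep("N", 31), "Z")), "'Y' and 'N'")
})

test_that("CDT codes map to the most specific procedure class, unknown falls back", {
  expect_identical(map_cdt_to_procedure_class("D2140"),
                   "ohd:amalgam_filling_restoration")
  expect_identical(map_cdt_to_procedure_class("D2392"),
                   "ohd:resin_filling_restoration")
  expect_identical(map_cdt_to_procedure_class("2392"),
                   "ohd:resin_filling_restoration")
  expect_identical(map_cdt_to_procedure_class("D2740"),
                   "ohd:crown_restoration_procedure")
  expect_warning(cls <- map_cdt_to_procedure_class("D9999"), "D9999")
  expect_identical(cls, "ohd:dental_procedure")
})

test_that("the minter is deterministic and injective over distinct keys", {
  m <- iri_minter()
  expect_identical(m$patient("P1"), m$patient("P1"))
  expect_false(m$patient("P1") == m$patient("P2"))
  expect_false(m$tooth("P1", 19) == m$surface("P1", 19, "M"))
  keys <- c(m$patient("P1"), m$provider("P1"), m$tooth("P1", 1),
            m$tooth("P11", 1), m$tooth("P1", 11), m$surface("P1", 1, "M"),
            m$visit("P1", as.Date("2000-01-02")))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("the two-surface resin example row translates to the full instance pattern", {
  row <- ph_rows(
    ~patient_id, ~provider_id, ~ada_code, ~tooth, ~surfaces, ~row_kind, ~encounter_date,
    "17", "21", "D2392", 19L, "MOD", "restoration", "2003-05-02")
  frag <- translate_restoration_row(row)

  types <- frag[frag$predicate == "rdf:type", ]
  expect_identical(sum(types$object %in% surface_codes()$class), 3L)
  expect_identical(sum(types$object == "ohd:resin_dental_restoration_material"), 1L)
  expect_identical(sum(types$object == "ohd:resin_filling_restoration"), 1L)
  expect_identical(sum(types$object == "ohd:CDT_D2392"), 1L)

  mat <- types$subject[types$object == "ohd:resin_dental_restoration_material"]
  expect_identical(sum(frag$predicate == "ohd:is_dental_restoration_of" &
                         frag$subject == mat), 3L)

  proc <- types$subject[types$object == "ohd:resin_filling_restoration"]
  realized <- frag$object[frag$predicate == "ohd:realizes" & frag$subject == proc]
  expect_identical(length(realized), 3L)  # patient, provider, material roles
  expect_true(any(frag$predicate == "ohd:occurrence_date" & frag$subject == proc &
                    frag$object == "2003-05-02"))
  expect_true(any(frag$predicate == "ohd:birth_date" & frag$obj_kind == "literal"))

  # idempotence: translating the same row twice gives identical fragments
  expect_identical(frag, translate_restoration_row(row))
})

test_that("fragment assertion count equals a hand-enumerated pattern checklist", {
  # one-surface amalgam row; the instance pattern enumerated edge by edge:
  #   patient: type + birth_date                                  = 2
  #   patient role: type + inheres_in                             = 2
  #   gender role: type + inheres_in                              = 2
  #   provider: type; provider role: type + inheres_in            = 3
  #   tooth: type + is_part_of patient                            = 2
  #   1 surface: type + is_part_of tooth                          = 2
  #   procedure: type + occurrence_date                           = 2
  #   procedure realizes 3 roles                                  = 3
  #   procedure has_participant patient/provider/tooth/material   = 4
  #   procedure has_specified_input material                      = 1
  #   material: type; material role: type + inheres_in            = 3
  #   material is_dental_restoration_of 1 surface                 = 1
  #   CDT code: type + is_about procedure                         = 2
  row <- ph_rows(
    ~patient_id, ~provider_id, ~ada_code, ~tooth, ~surfaces, ~row_kind,
    "P9", "prov03", "D2140", 30L, "O", "restoration")
  frag <- translate_restoration_row(row)
  expect_identical(nrow(frag), 29L)
})

test_that("surface-specific rows without tooth or surfaces are rejected", {
  row <- ph_rows(~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind,
                 "P1", "D2140", NA, NA, "restoration")
  expect_error(translate_restoration_row(row), "rejected")
  g <- translate_practice(row)
  expect_identical(g$rejected$row, 1L)
  expect_match(g$rejected$reason, "requires tooth and surfaces")
})

test_that("practice translation preserves counts per CDT code", {
  pr <- generate_practice(small_config(n_patients = 50, seed = 5))
  g <- translate_practice(pr)
  store_types <- g$assertions[g$assertions$predicate == "rdf:type", ]
  code_counts <- table(pr$rows$ada_code)
  for (code in names(code_counts)) {
    expect_identical(
      sum(store_types$object == paste0("ohd:CDT_", code)),
      as.integer(code_counts[[code]]),
      info = code)
  }
  # procedure individuals match total row count
  tab <- cdt_code_table()
  proc_classes <- unique(tab$class)
  n_proc <- sum(store_types$object %in% proc_classes)
  expect_identical(n_proc, nrow(pr$rows))
})

test_that("referent tracking: repeated work on one tooth reuses the tooth individual", {
  rows <- ph_rows(
    ~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind, ~encounter_date,
    "P1", "D2330", 8L, "M", "restoration", "2001-01-01",
    "P1", "D2330", 8L, "M", "refill", "2004-01-01")
  g <- translate_practice(rows)
  types <- g$assertions[g$assertions$predicate == "rdf:type", ]
  expect_identical(sum(types$object == "ohd:tooth_8"), 1L)
  expect_identical(sum(types$object == "ohd:resin_filling_restoration"), 2L)
  expect_identical(sum(types$object == "ohd:resin_dental_restoration_material"), 2L)
  # the shared surface individual is restored by two distinct materials
  surf <- types$subject[types$object == "ohd:mesial_surface_enamel"]
  expect_identical(length(surf), 1L)
  restorers <- g$assertions[g$assertions$predicate == "ohd:is_dental_restoration_of" &
                              g$assertions$object == surf, ]
  expect_identical(nrow(restorers), 2L)
})

test_that("no individual is asserted into two disjoint top-level categories", {
  pr <- generate_practice(small_config(n_patients = 30, seed = 8))
  g <- translate_practice(pr)
  ont <- build_mini_ohd()
  anc <- ohdsurv:::subclass_ancestors(ont)
  tops <- c("ohd:material_entity", "ohd:process", "ohd:role",
            "ohd:information_content_entity")
  top_of <- function(cls) tops[tops %in% c(cls, anc[[cls]])]
  types <- g$assertions[g$assertions$predicate == "rdf:type", ]
  per_ind <- tapply(types$object, types$subject, function(cls) {
    length(unique(unlist(lapply(cls, top_of))))
  })
  expect_true(all(per_ind <= 1))
})

test_that("missing-tooth finding rows become findings about the dentition", {
  rows <- ph_rows(
    ~patient_id, ~ada_code, ~tooth, ~surfaces, ~row_kind,
    "P2", NA, 5L, NA, "missing_tooth_finding")
  g <- translate_practice(rows)
  types <- g$assertions[g$assertions$predicate == "rdf:type", ]
  find <- types$subject[types$object == "ohd:missing_tooth_5_finding"]
  expect_identical(length(find), 1L)
  dent <- types$subject[types$object == "ohd:secondary_dentition"]
  about <- g$assertions[g$assertions$predicate == "ohd:is_about" &
                          g$assertions$subject == find, ]
  expect_identical(about$object, dent)
})

test_that("an empty dataset translates to an empty instance graph", {
  g <- translate_practice(generate_practice(small_config(n_patients = 0, seed = 1)))
  expect_identical(nrow(g$assertions), 0L)
  store <- load_and_materialize(build_mini_ohd(), g)
  expect_identical(nrow(store$base), 0L)
})
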