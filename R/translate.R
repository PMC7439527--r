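# Relational-row -> OWL instance translator.  Each patient_history row becomes
# a fragment of the instance graph: the patient and provider bearing their
# roles, the patient's tooth and its restored surface enamels as parts, the
# procedure realizing the roles, the portion of restoration material placed,
# and the CDT billing-code identifier about the procedure.  IRIs are minted
# deterministically from referent keys so the same real-world particular (a
# patient's tooth 19, say) always receives the same IRI across rows.

#' Parse a tooth-surface letter string
#'
#' @param text A (possibly empty) string over the charting letters
#'   M, O, D, B, F, L, I.
#' @return A tibble of the distinct surfaces in input order, with columns
#'   `letter`, `surface` and `class` (see [surface_codes()]).
#' @export
#' @examples
#' parse_surface_field("MOD")
parse_surface_field <- function(text) {
  if (length(text) != 1L || is.na(text)) text <- ""
  chars <- strsplit(text, "")[[1]]
  sc <- surface_codes()
  bad <- setdiff(chars, sc$letter)
  if (length(bad)) {
    stop("unknown surface letter '", bad[1], "' in \"", text, "\"")
  }
  sc[match(unique(chars), sc$letter), ]
}

#' Decode a 32-character tooth presence array
#'
#' Some dental EHR systems store a patient's dentition as a 32-character
#' array in which position i holds 'Y' when Universal tooth i is present.
#'
#' @param text A 32-character string over \{Y, N\}.
#' @return Integer vector of the 1-based positions holding 'Y'.
#' @export
#' @examples
#' decode_tooth_char_array("NNNNNYNNNNNNNNNNNNNNNNNNNNNNNNNN")  # tooth 6
decode_tooth_char_array <- function(text) {
  if (length(text) != 1L || is.na(text) || nchar(text) != 32L) {
    stop("tooth character array must have exactly 32 characters")
  }
  chars <- strsplit(text, "")[[1]]
  if (any(!chars %in% c("Y", "N"))) {
    stop("tooth character array must contain only 'Y' and 'N'")
  }
  which(chars == "Y")
}

#' Map a CDT billing code to a procedure class
#'
#' Known codes map to the most specific mini-ontology procedure class;
#' unknown codes fall back to the generic dental procedure class with a
#' warning (the code identifier itself is still attached to the translated
#' instance).
#'
#' @param ada_code CDT code string, with or without the leading `"D"`.
#' @param warn Warn on unknown codes (default `TRUE`).
#' @return A procedure class CURIE.
#' @export
#' @examples
#' map_cdt_to_procedure_class("D2140")
#' map_cdt_to_procedure_class("2392")
map_cdt_to_procedure_class <- function(ada_code, warn = TRUE) {
  code <- toupper(trimws(ada_code))
  code <- ifelse(startsWith(code, "D"), code, paste0("D", code))
  tab <- cdt_code_table()
  cls <- tab$class[match(code, tab$code)]
  if (anyNA(cls)) {
    if (warn) warning("unknown CDT code(s) mapped to generic dental procedure: ",
                      paste(unique(code[is.na(cls)]), collapse = ", "))
    cls[is.na(cls)] <- "ohd:dental_procedure"
  }
  cls
}

# ---- IRI minting ------------------------------------------------------------

#' Deterministic IRI minter
#'
#' Referent tracking requires that each real-world particular keep one IRI:
#' the minter derives the IRI from a stable key (patient id; patient + tooth
#' number; tooth + surface type; row identity for procedures and the material
#' portions they place), so the same key always yields the same IRI and
#' distinct keys yield distinct IRIs.
#'
#' @param namespace Prefix under which instance IRIs are minted (CURIE
#'   namespace label, default `"ex"`).
#' @return A list of key->IRI functions: `patient`, `provider`, `patient_role`,
#'   `provider_role`, `gender_role`, `tooth`, `surface`, `dentition`,
#'   `procedure`, `material`, `material_role`, `visit`, `cdt`, `finding`.
#' @export
iri_minter <- function(namespace = "ex") {
  key <- function(...) {
    parts <- lapply(list(...), function(a) gsub("[^A-Za-z0-9-]+", "-", as.character(a)))
    paste0(namespace, ":", do.call(paste, c(parts, sep = "_")))
  }
  list(
    patient = function(patient_id) key("patient", patient_id),
    provider = function(provider_id) key("provider", provider_id),
    patient_role = function(patient_id) key("patient-role", patient_id),
    provider_role = function(provider_id) key("provider-role", provider_id),
    gender_role = function(patient_id) key("gender-role", patient_id),
    tooth = function(patient_id, tooth) key("tooth", patient_id, tooth),
    surface = function(patient_id, tooth, letter)
      key("surface", patient_id, tooth, letter),
    dentition = function(patient_id) key("dentition", patient_id),
    procedure = function(row_id) key("procedure", row_id),
    material = function(row_id) key("material", row_id),
    material_role = function(row_id) key("material-role", row_id),
    visit = function(patient_id, date) key("visit", patient_id, format(date)),
    cdt = function(row_id) key("cdt", row_id),
    finding = function(row_id) key("finding", row_id)
  )
}

#' @noRd
assertions <- function(subject, predicate, object, obj_kind = "iri",
                       datatype = NA_character_) {
  tibble::tibble(subject = subject, predicate = predicate, object = object,
                 obj_kind = obj_kind, datatype = datatype)
}

date_literal <- function(d) format(d, "%Y-%m-%d")

# patient-level assertions shared by all of a patient's rows
#' @noRd
patient_assertions <- function(patient_id, provider_id, birth_date, gender,
                               minter) {
  pat <- minter$patient(patient_id)
  prov <- minter$provider(provider_id)
  dplyr::bind_rows(
    assertions(pat, "rdf:type", "ohd:human_dental_patient"),
    assertions(pat, "ohd:birth_date", date_literal(birth_date),
               "literal", "xsd:date"),
    assertions(minter$patient_role(patient_id), "rdf:type", "ohd:dental_patient_role"),
    assertions(minter$patient_role(patient_id), "ohd:inheres_in", pat),
    assertions(minter$gender_role(patient_id), "rdf:type",
               paste0("ohd:", gender, "_gender_role")),
    assertions(minter$gender_role(patient_id), "ohd:inheres_in", pat),
    assertions(prov, "rdf:type", "ohd:dental_health_care_provider"),
    assertions(minter$provider_role(provider_id), "rdf:type",
               "ohd:dental_health_care_provider_role"),
    assertions(minter$provider_role(provider_id), "ohd:inheres_in", prov)
  )
}

#' Translate a single restoration row into an instance-graph fragment
#'
#' Produces the full instance pattern for one restoration: patient and
#' provider with their roles, the gender role inhering in the patient, the
#' tooth (class `tooth N`) as part of the patient, one surface-enamel
#' individual per restored surface as part of the tooth, the procedure of the
#' CDT-mapped class with its occurrence date, the portion of restoration
#' material bearing a dental restoration material role and restoring each
#' surface, and the CDT identifier about the procedure.  Translation is
#' idempotent: the same row and minter always produce the identical fragment.
#'
#' @param row A one-row patient_history tibble of a restoration-kind row with
#'   tooth and surfaces present.
#' @param minter An [iri_minter()].
#' @param row_id Stable row identifier used to mint the procedure, material
#'   and code IRIs (defaults to patient id + date + code + tooth).
#' @return An assertion tibble.
#' @export
translate_restoration_row <- function(row, minter = iri_minter(),
                                      row_id = NULL) {
  stopifnot(nrow(row) == 1L)
  if (is.na(row$tooth) || is.na(row$surfaces) || !nzchar(row$surfaces)) {
    stop("restoration row rejected: tooth and surfaces are required for code ",
         row$ada_code)
  }
  if (is.null(row_id)) {
    row_id <- paste(row$patient_id, format(row$encounter_date), row$ada_code,
                    row$tooth, row$surfaces, sep = "-")
  }
  surf <- parse_surface_field(row$surfaces)
  cls <- map_cdt_to_procedure_class(row$ada_code)
  material_class <- if (cls == "ohd:amalgam_filling_restoration") {
    "ohd:amalgam_dental_restoration_material"
  } else "ohd:resin_dental_restoration_material"

  pat <- minter$patient(row$patient_id)
  prov <- minter$provider(row$provider_id)
  tooth <- minter$tooth(row$patient_id, row$tooth)
  surfaces <- vapply(surf$letter, function(l)
    minter$surface(row$patient_id, row$tooth, l), "")
  proc <- minter$procedure(row_id)
  mat <- minter$material(row_id)
  mat_role <- minter$material_role(row_id)
  cdt <- minter$cdt(row_id)
  code <- toupper(trimws(row$ada_code))
  code <- if (startsWith(code, "D")) code else paste0("D", code)

  dplyr::bind_rows(
    patient_assertions(row$patient_id, row$provider_id, row$birth_date,
                       row$gender, minter),
    assertions(tooth, "rdf:type", sprintf("ohd:tooth_%d", row$tooth)),
    assertions(tooth, "ohd:is_part_of", pat),
    assertions(surfaces, "rdf:type", surf$class),
    assertions(surfaces, "ohd:is_part_of", tooth),
    assertions(proc, "rdf:type", cls),
    assertions(proc, "ohd:occurrence_date", date_literal(row$encounter_date),
               "literal", "xsd:date"),
    assertions(proc, "ohd:realizes", c(minter$patient_role(row$patient_id),
                                       minter$provider_role(row$provider_id),
                                       mat_role)),
    assertions(proc, "ohd:has_participant", c(pat, prov, tooth, mat)),
    assertions(proc, "ohd:has_specified_input", mat),
    assertions(mat, "rdf:type", material_class),
    assertions(mat_role, "rdf:type", "ohd:dental_restoration_material_role"),
    assertions(mat_role, "ohd:inheres_in", mat),
    assertions(mat, "ohd:is_dental_restoration_of", surfaces),
    assertions(cdt, "rdf:type", paste0("ohd:CDT_", code)),
    assertions(cdt, "ohd:is_about", proc)
  )
}

#' Translate a practice dataset into an instance graph
#'
#' Translates every patient_history row: restoration-kind rows (initial
#' restorations and refills) via [translate_restoration_row()]; evaluations,
#' crowns, endodontic procedures and extractions as procedures realizing the
#' patient and provider roles (tooth-specific kinds participate their tooth);
#' missing-tooth-finding rows as finding individuals about the patient's
#' dentition.  Rows sharing a patient and encounter date are grouped under one
#' minted dental-visit individual: each procedure is part of its visit and
#' both carry the day-granularity occurrence date.  Rows that violate their
#' kind's requirements are collected in a rejection report instead of
#' silently dropped.
#'
#' @param x An `ohd_practice` or a patient_history rows tibble.
#' @param minter An [iri_minter()].
#' @return A list of class `ohd_instance_graph`: `assertions` (tibble),
#'   `rejected` (tibble of row index + reason).
#' @export
translate_practice <- function(x, minter = iri_minter()) {
  rows <- if (inherits(x, "ohd_practice")) x$rows else x
  n <- nrow(rows)
  out <- list()
  rejected <- tibble::tibble(row = integer(0), reason = character(0))
  if (n > 0L) {
    rows$..row_id <- paste0("r", formatC(seq_len(n), width = 7, flag = "0"))
    cdt_tab <- cdt_code_table()
    code <- toupper(trimws(rows$ada_code))
    code <- ifelse(is.na(code) | code == "", NA_character_,
                   ifelse(startsWith(code, "D"), code, paste0("D", code)))
    cls <- cdt_tab$class[match(code, cdt_tab$code)]
    surface_specific <- !is.na(cls) & cdt_tab$surface_specific[match(code, cdt_tab$code)]
    tooth_specific <- !is.na(cls) & cdt_tab$tooth_specific[match(code, cdt_tab$code)]
    is_finding <- !is.na(rows$row_kind) & rows$row_kind == "missing_tooth_finding"
    unknown <- is.na(cls) & !is_finding
    if (any(unknown & !is.na(code))) {
      warning("unknown CDT code(s) mapped to generic dental procedure: ",
              paste(unique(code[unknown & !is.na(code)]), collapse = ", "))
    }
    cls[unknown] <- "ohd:dental_procedure"

    bad_surface <- surface_specific & (is.na(rows$tooth) | is.na(rows$surfaces) |
                                         !nzchar(dplyr::coalesce(rows$surfaces, "")))
    bad_tooth <- tooth_specific & !surface_specific & is.na(rows$tooth)
    bad_finding <- is_finding & (is.na(rows$tooth) | rows$tooth < 1 | rows$tooth > 32)
    drop <- bad_surface | bad_tooth | bad_finding
    if (any(drop)) {
      rejected <- tibble::tibble(
        row = which(drop),
        reason = dplyr::case_when(
          bad_surface[drop] ~ "surface-specific code requires tooth and surfaces",
          bad_tooth[drop] ~ "tooth-specific code requires tooth",
          TRUE ~ "missing-tooth finding requires tooth 1-32"))
    }

    keep <- rows[!drop, , drop = FALSE]
    kcls <- cls[!drop]; kcode <- code[!drop]
    ksurf <- surface_specific[!drop]; ktooth <- tooth_specific[!drop]
    kfind <- is_finding[!drop]

    # per-patient demographics (one block per patient)
    pat_rows <- keep[!duplicated(keep$patient_id), , drop = FALSE]
    out$patients <- patient_assertions(
      pat_rows$patient_id, pat_rows$provider_id, pat_rows$birth_date,
      pat_rows$gender, minter)

    # visits: one individual per (patient, date)
    vis <- keep[!duplicated(paste(keep$patient_id, keep$encounter_date)), ,
                drop = FALSE]
    vis_iri <- minter$visit(vis$patient_id, vis$encounter_date)
    out$visits <- dplyr::bind_rows(
      assertions(vis_iri, "rdf:type", "ohd:dental_visit"),
      assertions(vis_iri, "ohd:occurrence_date", date_literal(vis$encounter_date),
                 "literal", "xsd:date"),
      assertions(vis_iri, "ohd:has_participant",
                 minter$patient(vis$patient_id)))

    # restoration-pattern rows (vectorized version of translate_restoration_row)
    r <- which(ksurf & !kfind)
    if (length(r)) {
      rr <- keep[r, , drop = FALSE]
      rid <- rr$..row_id
      proc <- minter$procedure(rid); mat <- minter$material(rid)
      mrole <- minter$material_role(rid); cdt <- minter$cdt(rid)
      tooth <- minter$tooth(rr$patient_id, rr$tooth)
      mat_cls <- ifelse(kcls[r] == "ohd:amalgam_filling_restoration",
                        "ohd:amalgam_dental_restoration_material",
                        "ohd:resin_dental_restoration_material")
      # explode surfaces
      letters_l <- strsplit(rr$surfaces, "")
      nlet <- lengths(letters_l)
      sidx <- rep(seq_along(r), nlet)
      slet <- unlist(letters_l)
      sc <- surface_codes()
      if (any(!slet %in% sc$letter)) {
        stop("unknown surface letter in restoration row(s)")
      }
      surf_iri <- minter$surface(rr$patient_id[sidx], rr$tooth[sidx], slet)
      out$restorations <- dplyr::bind_rows(
        assertions(tooth, "rdf:type", sprintf("ohd:tooth_%d", rr$tooth)),
        assertions(tooth, "ohd:is_part_of", minter$patient(rr$patient_id)),
        assertions(surf_iri, "rdf:type", sc$class[match(slet, sc$letter)]),
        assertions(surf_iri, "ohd:is_part_of", tooth[sidx]),
        assertions(proc, "rdf:type", kcls[r]),
        assertions(proc, "ohd:occurrence_date", date_literal(rr$encounter_date),
                   "literal", "xsd:date"),
        assertions(proc, "ohd:is_part_of",
                   minter$visit(rr$patient_id, rr$encounter_date)),
        assertions(proc, "ohd:realizes", minter$patient_role(rr$patient_id)),
        assertions(proc, "ohd:realizes", minter$provider_role(rr$provider_id)),
        assertions(proc, "ohd:realizes", mrole),
        assertions(proc, "ohd:has_participant", minter$patient(rr$patient_id)),
        assertions(proc, "ohd:has_participant", minter$provider(rr$provider_id)),
        assertions(proc, "ohd:has_participant", tooth),
        assertions(proc, "ohd:has_participant", mat),
        assertions(proc, "ohd:has_specified_input", mat),
        assertions(mat, "rdf:type", mat_cls),
        assertions(mrole, "rdf:type", "ohd:dental_restoration_material_role"),
        assertions(mrole, "ohd:inheres_in", mat),
        assertions(mat[sidx], "ohd:is_dental_restoration_of", surf_iri),
        assertions(cdt, "rdf:type", paste0("ohd:CDT_", kcode[r])),
        assertions(cdt, "ohd:is_about", proc))
    }

    # other procedures (evaluations, crowns, endodontic, extractions, unknown)
    o <- which(!ksurf & !kfind)
    if (length(o)) {
      oo <- keep[o, , drop = FALSE]
      rid <- oo$..row_id
      proc <- minter$procedure(rid)
      cdt <- minter$cdt(rid)
      has_tooth <- ktooth[o] & !is.na(oo$tooth)
      tooth <- ifelse(has_tooth, minter$tooth(oo$patient_id, oo$tooth), NA)
      known_code <- !is.na(kcode[o])
      out$others <- dplyr::bind_rows(
        assertions(proc, "rdf:type", kcls[o]),
        assertions(proc, "ohd:occurrence_date", date_literal(oo$encounter_date),
                   "literal", "xsd:date"),
        assertions(proc, "ohd:is_part_of",
                   minter$visit(oo$patient_id, oo$encounter_date)),
        assertions(proc, "ohd:realizes", minter$patient_role(oo$patient_id)),
        assertions(proc, "ohd:realizes", minter$provider_role(oo$provider_id)),
        assertions(proc, "ohd:has_participant", minter$patient(oo$patient_id)),
        assertions(proc, "ohd:has_participant", minter$provider(oo$provider_id)),
        if (any(has_tooth)) dplyr::bind_rows(
          assertions(tooth[has_tooth], "rdf:type",
                     sprintf("ohd:tooth_%d", oo$tooth[has_tooth])),
          assertions(tooth[has_tooth], "ohd:is_part_of",
                     minter$patient(oo$patient_id[has_tooth])),
          assertions(proc[has_tooth], "ohd:has_participant", tooth[has_tooth])),
        if (any(known_code)) dplyr::bind_rows(
          assertions(cdt[known_code], "rdf:type",
                     paste0("ohd:CDT_", kcode[o][known_code])),
          assertions(cdt[known_code], "ohd:is_about", proc[known_code])))
    }

    # missing-tooth findings: about the patient's dentition
    f <- which(kfind)
    if (length(f)) {
      ff <- keep[f, , drop = FALSE]
      find_iri <- minter$finding(ff$..row_id)
      dent <- minter$dentition(ff$patient_id)
      out$findings <- dplyr::bind_rows(
        assertions(dent, "rdf:type", "ohd:secondary_dentition"),
        assertions(dent, "ohd:is_part_of", minter$patient(ff$patient_id)),
        assertions(find_iri, "rdf:type",
                   sprintf("ohd:missing_tooth_%d_finding", ff$tooth)),
        assertions(find_iri, "ohd:is_about", dent))
    }
  }
  g <- dplyr::distinct(dplyr::bind_rows(out))
  structure(list(assertions = g, rejected = rejected),
            class = "ohd_instance_graph")
}

#' @export
print.ohd_instance_graph <- function(x, ...) {
  cat("<ohd_instance_graph> ", nrow(x$assertions), " assertions, ",
      dplyr::n_distinct(x$assertions$subject), " subjects",
      if (nrow(x$rejected)) paste0(", ", nrow(x$rejected), " rows rejected"),
      "\n", sep = "")
  invisible(x)
}
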