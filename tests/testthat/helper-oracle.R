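# Independent oracles, written against the raw patient_history table with
# plain loops; they share no code with the graph pipeline they check.

ORACLE_FILLING_CODES <- c("D2140", "D2150", "D2160", "D2161",
                          "D2330", "D2331", "D2332", "D2335", "D2392")
ORACLE_RESIN_CODES <- c("D2330", "D2331", "D2332", "D2335", "D2392")

# Brute-force first-event extraction per the failure rules: for each target
# restoration scan every strictly later row of the same patient; failures are
# a filling on the same tooth sharing >= 1 of the initially restored
# surfaces, or a crown (D2740) / endodontic (D3310) / extraction (D7140) of
# the same tooth; otherwise censor at the patient's last row date; exclude
# restorations with no later row.  Ties on the earliest date resolve
# extraction > endodontic > crown > refill.
oracle_cohort <- function(rows, target_codes = ORACLE_RESIN_CODES) {
  out <- list()
  for (p in unique(rows$patient_id)) {
    pr <- rows[rows$patient_id == p, , drop = FALSE]
    last_date <- max(pr$encounter_date)
    for (i in which(pr$ada_code %in% target_codes)) {
      r <- pr[i, ]
      later <- pr[pr$encounter_date > r$encounter_date, , drop = FALSE]
      if (nrow(later) == 0L) next
      cand <- later[!is.na(later$tooth) & later$tooth == r$tooth, , drop = FALSE]
      best_date <- as.Date(NA); best_kind <- NA_character_
      prio <- c(extraction = 1, endodontic = 2, crown = 3, refill = 4)
      if (nrow(cand)) {
        for (j in seq_len(nrow(cand))) {
          code <- cand$ada_code[j]
          kind <- if (code %in% ORACLE_FILLING_CODES) "refill"
          else if (code == "D2740") "crown"
          else if (code == "D3310") "endodontic"
          else if (code == "D7140") "extraction"
          else NA_character_
          if (is.na(kind)) next
          if (kind == "refill") {
            s2 <- cand$surfaces[j]
            if (is.na(s2) || !nzchar(s2)) next
            if (!any(strsplit(s2, "")[[1]] %in% strsplit(r$surfaces, "")[[1]])) next
          }
          d <- cand$encounter_date[j]
          if (is.na(best_date) || d < best_date ||
              (d == best_date && prio[kind] < prio[best_kind])) {
            best_date <- d; best_kind <- kind
          }
        }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        patient_id = p, restoration_date = r$encounter_date,
        tooth = r$tooth, surfaces = r$surfaces,
        outcome = if (is.na(best_date)) "censored" else "failed",
        outcome_date = if (is.na(best_date)) last_date else best_date,
        failure_kind = best_kind)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(patient_id = character(0),
                          restoration_date = as.Date(character(0)),
                          tooth = integer(0), surfaces = character(0),
                          outcome = character(0),
                          outcome_date = as.Date(character(0)),
                          failure_kind = character(0))
  }
  dplyr::arrange(res, patient_id, restoration_date, tooth, surfaces,
                 outcome, outcome_date)
}

# normalize a store cohort to the oracle's shape for multiset comparison
cohort_as_oracle <- function(cohort) {
  cohort |>
    dplyr::transmute(
      patient_id = sub("^ex:patient_", "", patient),
      restoration_date, tooth, surfaces, outcome, outcome_date, failure_kind) |>
    dplyr::arrange(patient_id, restoration_date, tooth, surfaces,
                   outcome, outcome_date)
}

# sort-and-link chain oracle over (enc, patient, date)
oracle_chain <- function(enc) {
  nxt <- list(); subs <- list()
  for (p in unique(enc$patient)) {
    e <- enc[enc$patient == p, , drop = FALSE]
    dates <- sort(unique(e$date))
    pairs <- function(a, b) {
      f <- rep(a, times = length(b))
      t <- rep(b, each = length(a))
      tibble::tibble(from = f, to = t)
    }
    for (k in seq_along(dates)) {
      from <- e$enc[e$date == dates[k]]
      if (k < length(dates)) {
        nxt[[length(nxt) + 1L]] <- pairs(from, e$enc[e$date == dates[k + 1L]])
      }
      for (m in seq_along(dates)) {
        if (m > k) {
          subs[[length(subs) + 1L]] <- pairs(from, e$enc[e$date == dates[m]])
        }
      }
    }
  }
  list(next_edges = dplyr::arrange(dplyr::bind_rows(nxt), from, to),
       subsequent = dplyr::arrange(dplyr::bind_rows(subs), from, to))
}

# hand product-limit computation (plain cumprod over sorted event times)
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut)); s <- 1
  for (k in seq_along(ut)) {
    n <- sum(time >= ut[k]); d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n)
    surv[k] <- s
  }
  tibble::tibble(time = ut, surv = surv)
}
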