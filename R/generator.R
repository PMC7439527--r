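# Synthetic dental-practice generator.  Emulates a flat patient_history
# extract from a single practice's EHR (one row per billed procedure) with
# known ground-truth restoration survival: failure times follow a Weibull
# proportional-hazards model over four binary covariates (gender, age group
# at restoration, tooth position, surface count), optionally mixed with an
# early-failure exponential component.

ANTERIOR_TEETH <- c(6:11, 22:27)  # canine-to-canine, both arches

#' Is a Universal-numbered tooth posterior?
#'
#' Anterior teeth are Universal numbers 6-11 and 22-27 (canine to canine);
#' every other permanent tooth is posterior.
#'
#' @param tooth Integer vector of tooth numbers (1-32).
#' @return Logical vector.
#' @export
is_posterior_tooth <- function(tooth) !(tooth %in% ANTERIOR_TEETH)

#' Generator configuration
#'
#' Assembles and validates the configuration for [generate_practice()].
#' Defaults encode the emulated study conditions: a 1999-2011 observation
#' window, a majority-female panel, a baseline Weibull with 12-year median
#' survival, hazard ratios for male gender (1.16), age 40+ at restoration
#' (1.40), posterior tooth (0.77) and multi-surface restoration (0.88), and an
#' early-failure mixture (weight 0.15, mean 0.8 years) producing elevated
#' hazard in the first two years.
#'
#' @param n_patients Number of patients.
#' @param window_start,window_end Observation window (ISO dates).
#' @param p_female Probability a patient is female.
#' @param birth_year_range Two-element integer vector of birth years.
#' @param p_panel Probability a patient belongs to the practice's standing
#'   panel, i.e. their first recorded visit falls within the first year of the
#'   window; otherwise the first visit is uniform over the window.
#' @param visit_gap_months List with `meanlog` and `sdlog` of the log-normal
#'   gap (months) between successive scheduled visits.
#' @param p_restoration_per_visit Probability a scheduled visit includes a new
#'   restoration (on a tooth not previously restored for that patient).
#' @param p_multi_surface Probability a restoration covers more than one
#'   surface.
#' @param p_resin Probability the restoration material is resin (else amalgam).
#' @param baseline_shape Weibull shape k > 0 of the baseline failure-time
#'   distribution.
#' @param baseline_median_years Baseline median survival in years; the scale
#'   is calibrated with [calibrate_baseline_scale()].
#' @param hr_male,hr_age40plus,hr_posterior,hr_multisurface Hazard ratios
#'   (> 0) applied multiplicatively on the baseline hazard.
#' @param early_failure_weight Mixture weight in `[0,1]` of the early-failure
#'   exponential component (independent of covariates).
#' @param early_failure_mean_years Mean of the early-failure component.
#' @param failure_type_probs Named probabilities over
#'   `c("refill", "crown", "endodontic", "extraction")`; must sum to 1.
#'   Refills re-enter the risk process with their own sampled failure time;
#'   the other kinds are terminal for the tooth.
#' @param n_providers Number of providers in the practice.
#' @param seed Integer seed; mandatory, every draw is reproducible under it.
#' @return A validated list of class `ohd_generator_config`.
#' @export
generator_config <- function(n_patients = 500,
                             window_start = "1999-01-01",
                             window_end = "2011-12-31",
                             p_female = 0.56,
                             birth_year_range = c(1930, 1985),
                             p_panel = 0.5,
                             visit_gap_months = list(meanlog = log(8), sdlog = 0.6),
                             p_restoration_per_visit = 0.25,
                             p_multi_surface = 0.5,
                             p_resin = 0.65,
                             baseline_shape = 1.2,
                             baseline_median_years = 12,
                             hr_male = 1.16,
                             hr_age40plus = 1.40,
                             hr_posterior = 0.77,
                             hr_multisurface = 0.88,
                             early_failure_weight = 0.15,
                             early_failure_mean_years = 0.8,
                             failure_type_probs = c(refill = 0.55, crown = 0.20,
                                                    endodontic = 0.15, extraction = 0.10),
                             n_providers = 6,
                             seed = NULL) {
  cfg <- as.list(environment())
  probs <- c(p_female, p_panel, p_restoration_per_visit, p_multi_surface,
             p_resin, early_failure_weight)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory for generation")
  cfg$seed <- as.integer(seed)
  ws <- as.Date(window_start); we <- as.Date(window_end)
  if (is.na(ws) || is.na(we) || ws >= we) stop("window_start must precede window_end")
  cfg$window_start <- ws; cfg$window_end <- we
  if (!setequal(names(failure_type_probs),
                c("refill", "crown", "endodontic", "extraction")) ||
      abs(sum(failure_type_probs) - 1) > 1e-8 || any(failure_type_probs < 0)) {
    stop("failure_type_probs must be named over refill/crown/endodontic/extraction and sum to 1")
  }
  if (baseline_shape <= 0 || baseline_median_years <= 0) {
    stop("baseline_shape and baseline_median_years must be positive")
  }
  if (any(c(hr_male, hr_age40plus, hr_posterior, hr_multisurface) <= 0)) {
    stop("hazard ratios must be positive")
  }
  if (early_failure_mean_years <= 0) stop("early_failure_mean_years must be positive")
  if (n_patients < 0) stop("n_patients must be non-negative")
  if (!is.list(visit_gap_months) ||
      !all(c("meanlog", "sdlog") %in% names(visit_gap_months))) {
    stop("visit_gap_months must be a list with meanlog and sdlog")
  }
  structure(cfg, class = "ohd_generator_config")
}

#' Read a generator configuration from YAML
#'
#' Unknown keys are rejected; dates and the failure-type map are validated by
#' [generator_config()].
#'
#' @param path Path to a YAML file whose keys are `generator_config()`
#'   arguments.
#' @return An `ohd_generator_config`.
#' @export
read_generator_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(generator_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad)) stop("unknown generator config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$failure_type_probs)) y$failure_type_probs <- unlist(y$failure_type_probs)
  if (!is.null(y$birth_year_range)) y$birth_year_range <- unlist(y$birth_year_range)
  do.call(generator_config, y)
}

#' Calibrate the baseline Weibull scale from a target median
#'
#' For a Weibull with shape `k`, the scale giving median `m` is
#' `m / log(2)^(1/k)`, so that `S(m) = exp(-(m/lambda)^k) = 1/2`.
#'
#' @param shape Weibull shape k > 0.
#' @param median_years Target median in years, > 0.
#' @return The scale lambda (years).
#' @export
#' @examples
#' calibrate_baseline_scale(1, 12)   # 12 / log(2)
calibrate_baseline_scale <- function(shape, median_years) {
  if (!is.finite(shape) || shape <= 0) stop("shape must be positive")
  if (!is.finite(median_years) || median_years <= 0) stop("median_years must be positive")
  median_years / log(2)^(1 / shape)
}

#' Sample restoration failure times
#'
#' Draws from the generator's failure-time model: with probability
#' `early_failure_weight` an exponential with mean `early_failure_mean_years`;
#' otherwise a Weibull proportional-hazards draw
#' `T = lambda * (-log(U) / exp(lp))^(1/k)` with linear predictor
#' `lp = sum(log(hr_i) * x_i)` over the four binary covariates.  Uses the
#' session RNG; seed with `set.seed()` (or via [generate_practice()]) for
#' reproducibility.
#'
#' @param covariates Data frame with logical columns `male`, `age_ge_40`,
#'   `posterior`, `multisurface`; one row per draw.
#' @param config An `ohd_generator_config`.
#' @return Numeric vector of failure times in years.
#' @export
sample_failure_time <- function(covariates, config) {
  stopifnot(inherits(config, "ohd_generator_config"))
  n <- nrow(covariates)
  if (n == 0L) return(numeric(0))
  lambda <- calibrate_baseline_scale(config$baseline_shape, config$baseline_median_years)
  lp <- log(config$hr_male) * covariates$male +
    log(config$hr_age40plus) * covariates$age_ge_40 +
    log(config$hr_posterior) * covariates$posterior +
    log(config$hr_multisurface) * covariates$multisurface
  early <- stats::runif(n) < config$early_failure_weight
  t_main <- lambda * (-log(stats::runif(n)) / exp(lp))^(1 / config$baseline_shape)
  t_early <- stats::rexp(n, rate = 1 / config$early_failure_mean_years)
  ifelse(early, t_early, t_main)
}

# surface pools by tooth position; ordering of letters in a surface string is
# canonical charting order M O D B F L I
SURFACE_ORDER <- c("M", "O", "D", "B", "F", "L", "I")
POSTERIOR_SURFACES <- c("M", "O", "D", "B", "L")
ANTERIOR_SURFACES <- c("M", "D", "F", "L", "I")

#' @noRd
canonical_surface_string <- function(letters_list) {
  vapply(letters_list, function(s) {
    paste(SURFACE_ORDER[SURFACE_ORDER %in% s], collapse = "")
  }, "")
}

# CDT code for a filling given material, surface count and tooth position
#' @noRd
filling_code <- function(material, n_surfaces, posterior) {
  n <- pmin(n_surfaces, 4L)
  amalgam <- c("D2140", "D2150", "D2160", "D2161")[n]
  resin <- ifelse(posterior & n == 2L, "D2392",
                  c("D2330", "D2331", "D2332", "D2335")[n])
  ifelse(material == "amalgam", amalgam, resin)
}

#' Generate a synthetic practice dataset
#'
#' Simulates a dental practice over the configured window: per-patient
#' demographics, a scheduled visit sequence with log-normal gaps, an oral
#' evaluation at every visit, new restorations at visits (distinct teeth per
#' patient) with sampled surfaces and material, and for every restoration a
#' true failure time from the proportional-hazards model.  A failure observed
#' before the patient's last scheduled visit is emitted as an event row at its
#' own encounter date (a refill sharing at least one original surface, or a
#' crown, endodontic procedure or extraction of the tooth); refills re-enter
#' the risk process as new restorations.  Unfailed restorations are censored
#' implicitly by the end of the patient's record.  All dates have day
#' granularity and the output is fully reproducible under `config$seed`.
#'
#' @param config An `ohd_generator_config`.
#' @return An `ohd_practice`: list with `rows` (the patient_history tibble,
#'   sorted by patient and encounter date), `ground_truth` (one row per
#'   restoration instance with true covariates, true and observed times, and
#'   censoring cause) and `config`.
#' @export
generate_practice <- function(config) {
  stopifnot(inherits(config, "ohd_generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  win_days <- as.integer(config$window_end - config$window_start)

  empty_rows <- tibble::tibble(
    patient_id = character(0), provider_id = character(0),
    birth_date = as.Date(character(0)), gender = character(0),
    encounter_date = as.Date(character(0)), ada_code = character(0),
    tooth = integer(0), surfaces = character(0), row_kind = character(0))
  empty_gt <- tibble::tibble(
    gt_id = integer(0), patient_id = character(0),
    encounter_date = as.Date(character(0)), ada_code = character(0),
    tooth = integer(0), surfaces = character(0), material = character(0),
    male = logical(0), age_ge_40 = logical(0), posterior = logical(0),
    multisurface = logical(0), true_time_years = numeric(0),
    observed_event = integer(0), observed_time_years = numeric(0),
    failure_kind = character(0), same_day = logical(0), has_followup = logical(0))
  if (n == 0L) {
    return(structure(list(rows = empty_rows, ground_truth = empty_gt,
                          config = config), class = "ohd_practice"))
  }

  patients <- tibble::tibble(
    pid = seq_len(n),
    patient_id = sprintf("P%05d", seq_len(n)),
    provider_id = sprintf("prov%02d", sample.int(config$n_providers, n, replace = TRUE)),
    gender = ifelse(stats::runif(n) < config$p_female, "female", "male"),
    birth_date = config$window_start - as.integer(
      stats::runif(n,
                   min = as.numeric(config$window_start -
                                      as.Date(sprintf("%d-12-31", config$birth_year_range[2]))),
                   max = as.numeric(config$window_start -
                                      as.Date(sprintf("%d-01-01", config$birth_year_range[1]))))),
    panel = stats::runif(n) < config$p_panel)
  patients$entry <- as.integer(ifelse(
    patients$panel,
    stats::runif(n, 0, min(365, win_days - 1)),
    stats::runif(n, 0, win_days - 1)))

  # scheduled visit offsets (days from window start)
  G <- 80L
  gaps <- matrix(pmax(1, round(stats::rlnorm(
    n * G, config$visit_gap_months$meanlog,
    config$visit_gap_months$sdlog) * 30.4375)), nrow = n)
  offs <- patients$entry + cbind(0L, t(apply(gaps, 1, cumsum)))
  visits <- tibble::tibble(
    pid = rep(patients$pid, times = G + 1L),
    offset = as.integer(offs))
  visits <- visits[visits$offset <= win_days, , drop = FALSE]
  visits <- dplyr::arrange(visits, .data$pid, .data$offset)
  obs_end <- tapply(visits$offset, visits$pid, max)  # last scheduled visit

  # new restorations at visits, on distinct teeth per patient
  rest <- visits[stats::runif(nrow(visits)) < config$p_restoration_per_visit, ,
                 drop = FALSE]
  rest <- rest |>
    dplyr::group_by(.data$pid) |>
    dplyr::filter(dplyr::row_number() <= 32L) |>
    dplyr::mutate(tooth = sample(32L, dplyr::n())) |>
    dplyr::ungroup()

  m <- nrow(rest)
  rest$posterior <- is_posterior_tooth(rest$tooth)
  rest$material <- ifelse(stats::runif(m) < config$p_resin, "resin", "amalgam")
  multi <- stats::runif(m) < config$p_multi_surface
  n_surf <- ifelse(multi, 1L + sample(3L, m, replace = TRUE, prob = c(0.6, 0.3, 0.1)), 1L)
  rest$surfaces <- canonical_surface_string(lapply(seq_len(m), function(i) {
    pool <- if (rest$posterior[i]) POSTERIOR_SURFACES else ANTERIOR_SURFACES
    sample(pool, min(n_surf[i], length(pool)))
  }))

  # iterate failure chains; refills re-enter as new restorations
  gt <- list(); event_rows <- list()
  active <- rest
  iter <- 0L
  while (nrow(active) > 0L && iter < 64L) {
    iter <- iter + 1L
    a <- active
    k <- nrow(a)
    date_d <- a$offset
    age <- as.numeric(config$window_start + date_d -
                        patients$birth_date[a$pid]) / 365.25
    cov <- tibble::tibble(
      male = patients$gender[a$pid] == "male",
      age_ge_40 = age >= 40,
      posterior = a$posterior,
      multisurface = nchar(a$surfaces) > 1L)
    tt <- sample_failure_time(cov, config)
    fail_off <- date_d + as.integer(round(tt * 365.25))
    end <- as.integer(obs_end[as.character(a$pid)])
    observed <- fail_off <= end
    kind <- sample(names(config$failure_type_probs), k, replace = TRUE,
                   prob = config$failure_type_probs)
    kind[!observed] <- NA_character_

    gt[[iter]] <- tibble::tibble(
      pid = a$pid, offset = date_d,
      ada_code = filling_code(a$material, nchar(a$surfaces), a$posterior),
      tooth = a$tooth, surfaces = a$surfaces, material = a$material,
      male = cov$male, age_ge_40 = cov$age_ge_40, posterior = cov$posterior,
      multisurface = cov$multisurface,
      true_time_years = tt,
      observed_event = as.integer(observed),
      observed_time_years = ifelse(observed, (fail_off - date_d) / 365.25,
                                   (end - date_d) / 365.25),
      failure_kind = kind,
      same_day = observed & fail_off == date_d)

    hit <- which(observed)
    if (length(hit)) {
      h <- a[hit, , drop = FALSE]
      hkind <- kind[hit]; hoff <- fail_off[hit]
      # refills copy a non-empty subset of the failed restoration's surfaces
      is_refill <- hkind == "refill"
      new_surf <- h$surfaces
      if (any(is_refill)) {
        new_surf[is_refill] <- canonical_surface_string(
          lapply(which(is_refill), function(i) {
            s <- strsplit(h$surfaces[i], "")[[1]]
            keep <- s[stats::runif(length(s)) < 0.6]
            if (!length(keep)) keep <- sample(s, 1L)
            keep
          }))
      }
      code <- ifelse(is_refill,
                     filling_code(h$material, nchar(new_surf), h$posterior),
                     c(crown = "D2740", endodontic = "D3310",
                       extraction = "D7140")[hkind])
      event_rows[[iter]] <- tibble::tibble(
        pid = h$pid, offset = hoff, ada_code = unname(code),
        tooth = h$tooth,
        surfaces = ifelse(is_refill, new_surf, NA_character_),
        row_kind = hkind)
      active <- tibble::tibble(
        pid = h$pid[is_refill], offset = hoff[is_refill],
        tooth = h$tooth[is_refill], posterior = h$posterior[is_refill],
        material = h$material[is_refill], surfaces = new_surf[is_refill])
    } else {
      active <- active[0, , drop = FALSE]
    }
  }
  gt <- dplyr::bind_rows(gt)
  events <- dplyr::bind_rows(event_rows)

  make_rows <- function(pid, offset, ada_code, tooth, surfaces, row_kind) {
    tibble::tibble(
      patient_id = patients$patient_id[pid],
      provider_id = patients$provider_id[pid],
      birth_date = patients$birth_date[pid],
      gender = patients$gender[pid],
      encounter_date = config$window_start + offset,
      ada_code = ada_code, tooth = as.integer(tooth), surfaces = surfaces,
      row_kind = row_kind)
  }
  rows <- dplyr::bind_rows(
    make_rows(visits$pid, visits$offset, "D0120", NA_integer_,
              NA_character_, "evaluation"),
    make_rows(rest$pid, rest$offset,
              filling_code(rest$material, nchar(rest$surfaces), rest$posterior),
              rest$tooth, rest$surfaces, "restoration"),
    if (nrow(events)) make_rows(events$pid, events$offset, events$ada_code,
                                events$tooth, events$surfaces, events$row_kind)
  )
  rows <- dplyr::arrange(rows, .data$patient_id, .data$encounter_date)

  # finalize ground truth: follow-up flag and identifiers
  last_row <- rows |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(last_date = max(.data$encounter_date), .groups = "drop")
  gt_out <- gt |>
    dplyr::mutate(
      gt_id = dplyr::row_number(),
      patient_id = patients$patient_id[.data$pid],
      encounter_date = config$window_start + .data$offset) |>
    dplyr::left_join(last_row, by = "patient_id") |>
    dplyr::mutate(has_followup = .data$last_date > .data$encounter_date) |>
    dplyr::select(dplyr::all_of(names(empty_gt)))

  structure(list(rows = rows, ground_truth = gt_out, config = config),
            class = "ohd_practice")
}

#' @export
print.ohd_practice <- function(x, ...) {
  cat("<ohd_practice> ", dplyr::n_distinct(x$rows$patient_id), " patients, ",
      nrow(x$rows), " rows (", sum(x$ground_truth$observed_event),
      " observed failures / ", nrow(x$ground_truth), " restorations)\n", sep = "")
  invisible(x)
}

# ---- patient_history CSV ----------------------------------------------------

PATIENT_HISTORY_COLUMNS <- c("patient_id", "provider_id", "birth_date", "gender",
                             "encounter_date", "ada_code", "tooth", "surfaces",
                             "row_kind")

#' Write a patient_history CSV
#'
#' Header-stable CSV with ISO-8601 dates; absent tooth/surface fields are
#' written as empty cells.
#'
#' @param x An `ohd_practice` or a patient_history rows tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_history_csv <- function(x, path) {
  rows <- if (inherits(x, "ohd_practice")) x$rows else x
  stopifnot(identical(names(rows), PATIENT_HISTORY_COLUMNS))
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' Read a patient_history CSV
#'
#' Validates each row (dates, gender, CDT code shape, tooth range, surface
#' alphabet) and reports offending line numbers.
#'
#' @param path Input path.
#' @return A patient_history rows tibble.
#' @export
read_patient_history_csv <- function(path) {
  rows <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    provider_id = readr::col_character(),
    birth_date = readr::col_date(),
    gender = readr::col_character(),
    encounter_date = readr::col_date(),
    ada_code = readr::col_character(),
    tooth = readr::col_integer(),
    surfaces = readr::col_character(),
    row_kind = readr::col_character()), progress = FALSE)
  if (!identical(names(rows), PATIENT_HISTORY_COLUMNS)) {
    stop("patient_history header mismatch; expected: ",
         paste(PATIENT_HISTORY_COLUMNS, collapse = ","))
  }
  bad <- function(cond) which(cond) + 1L  # header line offset
  problems <- c(
    if (length(i <- bad(is.na(rows$encounter_date))))
      paste0("line ", i, ": missing/invalid encounter_date"),
    if (length(i <- bad(is.na(rows$birth_date))))
      paste0("line ", i, ": missing/invalid birth_date"),
    if (length(i <- bad(!rows$gender %in% c("female", "male"))))
      paste0("line ", i, ": gender must be female or male"),
    if (length(i <- bad(!is.na(rows$tooth) & (rows$tooth < 1L | rows$tooth > 32L))))
      paste0("line ", i, ": tooth out of range 1-32"),
    if (length(i <- bad(!is.na(rows$surfaces) &
                          grepl(paste0("[^", paste(SURFACE_ORDER, collapse = ""), "]"),
                                rows$surfaces))))
      paste0("line ", i, ": invalid surface letter")
  )
  if (length(problems)) {
    stop("invalid patient_history rows:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "))
  }
  rows
}
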