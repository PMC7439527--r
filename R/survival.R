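# Survival stage: event-table construction from cohort records, a native
# product-limit (Kaplan-Meier) estimator with Greenwood confidence bands, Cox
# proportional-hazards fits (via survival::coxph) rendered as percent hazard
# change, and a kernel-smoothed hazard-rate curve.

DAYS_PER_YEAR <- 365.25

#' Build the survival event table from cohort records
#'
#' One event record per first-event cohort record: follow-up time in years
#' (`(outcome date - restoration date) / 365.25`), event indicator, and the
#' four analysis correlates — gender, age group at restoration (40 and over
#' vs under 40), tooth position (posterior vs anterior, canine-to-canine
#' convention) and surface group (multiple vs single surface).  Zero-duration
#' records are dropped with a warning; records whose patient lacks a birth
#' date or gender are dropped and counted.
#'
#' @param cohort First-event records from [extract_restoration_cohort()].
#' @param demographics Patient demographics from [patient_demographics()]
#'   (columns `patient`, `birth_date`, `gender`).
#' @return A tibble of event records with columns `restoration`, `patient`,
#'   `time_years`, `event`, `failure_kind`, `gender`, `age_ge_40`,
#'   `posterior`, `multisurface`.
#' @export
build_event_table <- function(cohort, demographics) {
  ev <- cohort |>
    dplyr::left_join(demographics, by = "patient") |>
    dplyr::mutate(
      time_years = as.numeric(.data$outcome_date - .data$restoration_date) /
        DAYS_PER_YEAR,
      event = as.integer(.data$outcome == "failed"),
      age_ge_40 = as.numeric(.data$restoration_date - .data$birth_date) /
        DAYS_PER_YEAR >= 40,
      posterior = is_posterior_tooth(.data$tooth),
      multisurface = nchar(.data$surfaces) > 1L)
  missing_demo <- is.na(ev$birth_date) | is.na(ev$gender)
  if (any(missing_demo)) {
    warning(sum(missing_demo), " record(s) dropped for missing birth date or gender")
    ev <- ev[!missing_demo, , drop = FALSE]
  }
  zero <- ev$time_years <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-duration record(s) dropped")
    ev <- ev[!zero, , drop = FALSE]
  }
  ev |>
    dplyr::select(dplyr::all_of(c("restoration", "patient", "time_years",
                                  "event", "failure_kind", "gender",
                                  "age_ge_40", "posterior", "multisurface")))
}

#' Kaplan-Meier product-limit fit
#'
#' Native product-limit estimator with Greenwood standard errors and
#' log-scale 95% confidence bands, optionally stratified by one covariate.
#' The median is the smallest time at which the survival estimate drops to
#' 0.5 or below (undefined — `NA` — when the curve never reaches 0.5).
#'
#' @param events Event table from [build_event_table()], or any tibble with
#'   `time_years` and `event`.
#' @param group_by Optional name of a column to stratify by.
#' @param conf_level Confidence level for the bands (default 0.95).
#' @return An object of class `ohd_km`: list with `curve` (tibble: `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `se`, `lower`, `upper`)
#'   and `medians` (tibble: `group`, `n`, `events`, `median`).
#' @export
km_fit <- function(events, group_by = NULL, conf_level = 0.95) {
  if (nrow(events) == 0L) stop("no event records to fit")
  groups <- if (is.null(group_by)) {
    rep("overall", nrow(events))
  } else {
    as.character(events[[group_by]])
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  one <- function(time, status) {
    ord <- order(time)
    time <- time[ord]; status <- status[ord]
    ut <- sort(unique(time[status == 1L]))
    n_risk <- vapply(ut, function(t) sum(time >= t), 0L)
    n_event <- vapply(ut, function(t) sum(time == t & status == 1L), 0L)
    n_censor <- vapply(ut, function(t) sum(time == t & status == 0L), 0L)
    surv <- cumprod(1 - n_event / n_risk)
    gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
    gw[!is.finite(gw)] <- Inf
    se <- surv * sqrt(gw)
    # log-scale bands, the survfit default
    lower <- exp(log(surv) - z * sqrt(gw))
    upper <- pmin(exp(log(surv) + z * sqrt(gw)), 1)
    lower[surv == 0] <- 0; upper[surv == 0] <- 0
    tibble::tibble(time = ut, n_risk = as.integer(n_risk),
                   n_event = as.integer(n_event),
                   n_censor = as.integer(n_censor),
                   surv = surv, se = se, lower = lower, upper = upper)
  }
  curves <- lapply(split(seq_len(nrow(events)), groups), function(idx) {
    one(events$time_years[idx], events$event[idx])
  })
  curve <- dplyr::bind_rows(curves, .id = "group")
  med_tab <- curve |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median = if (any(.data$surv <= 0.5))
      min(.data$time[.data$surv <= 0.5]) else NA_real_, .groups = "drop")
  medians <- tibble::tibble(group = groups, event = events$event) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$event),
                     .groups = "drop") |>
    dplyr::left_join(med_tab, by = "group") |>
    dplyr::select(dplyr::all_of(c("group", "n", "events", "median")))
  structure(list(curve = curve, medians = medians,
                 group_by = group_by %||% "overall",
                 conf_level = conf_level),
            class = "ohd_km")
}

#' @export
print.ohd_km <- function(x, ...) {
  cat("<ohd_km> product-limit fit",
      if (!identical(x$group_by, "overall")) paste0(" by ", x$group_by),
      "\n", sep = "")
  print(x$medians)
  invisible(x)
}

# standard-error-based uncertainty of the KM median: Greenwood SE at the
# median divided by a local density estimate of the curve's slope there
#' @noRd
km_median_se <- function(km, group = NULL, window = 2) {
  cv <- km$curve
  if (!is.null(group)) cv <- cv[cv$group == group, , drop = FALSE]
  med <- km$medians$median[if (is.null(group)) 1L else
    match(group, km$medians$group)]
  if (is.na(med)) return(NA_real_)
  at <- which.min(abs(cv$time - med))
  near <- cv[cv$time >= med - window & cv$time <= med + window, , drop = FALSE]
  if (nrow(near) < 2L) return(NA_real_)
  slope <- abs((near$surv[nrow(near)] - near$surv[1]) /
                 (near$time[nrow(near)] - near$time[1]))
  if (slope == 0) return(NA_real_)
  cv$se[at] / slope
}

#' Cox proportional-hazards fit over the four correlates
#'
#' Joint fit of gender (male vs female), age group (40+ vs under 40), tooth
#' position (posterior vs anterior) and surface group (multiple vs single)
#' with `survival::coxph()`; `mode = "univariate"` fits each correlate
#' separately.  Effects are rendered as percent hazard change,
#' `(exp(beta) - 1) * 100`, labelled as an increase or decrease.
#'
#' @param events Event table from [build_event_table()].
#' @param mode `"joint"` (default) or `"univariate"`.
#' @return An object of class `ohd_cox`: list with `table` (tibble: `term`,
#'   `beta`, `se`, `p`, `hr`, `hr_lower`, `hr_upper`, `pct_change`,
#'   `direction`, `label`), `n`, `n_events`, `mode` and the underlying
#'   `fits`.
#' @export
cox_fit <- function(events, mode = c("joint", "univariate")) {
  mode <- match.arg(mode)
  if (sum(events$event) == 0L) stop("no failures; cannot fit a hazard model")
  df <- events |>
    dplyr::transmute(
      time = .data$time_years, status = .data$event,
      male = .data$gender == "male",
      age_40plus = .data$age_ge_40,
      posterior = .data$posterior,
      multisurface = .data$multisurface)
  terms <- c("male", "age_40plus", "posterior", "multisurface")
  fits <- if (mode == "joint") {
    list(joint = survival::coxph(
      survival::Surv(time, status) ~ male + age_40plus + posterior + multisurface,
      data = df))
  } else {
    stats::setNames(lapply(terms, function(tm) {
      survival::coxph(stats::reformulate(tm, "survival::Surv(time, status)"),
                      data = df)
    }), terms)
  }
  rows <- lapply(fits, function(fit) {
    s <- summary(fit)
    tibble::tibble(
      term = sub("TRUE$", "", rownames(s$coefficients)),
      beta = s$coefficients[, "coef"],
      se = s$coefficients[, "se(coef)"],
      p = s$coefficients[, "Pr(>|z|)"],
      hr = s$coefficients[, "exp(coef)"],
      hr_lower = s$conf.int[, "lower .95"],
      hr_upper = s$conf.int[, "upper .95"])
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      pct_change = (.data$hr - 1) * 100,
      direction = ifelse(.data$pct_change >= 0, "increase", "decrease"),
      label = render_hazard_difference(.data$hr))
  structure(list(table = tab, n = nrow(df), n_events = sum(df$status),
                 mode = mode, fits = fits),
            class = "ohd_cox")
}

#' Render a hazard ratio as a percent-change label
#'
#' `(exp(beta) - 1) * 100`, labelled "increase" when positive and "decrease"
#' when negative; the mapping is involution-consistent: an x% decrease
#' corresponds to HR `1 - x/100`.
#'
#' @param hr Hazard ratio(s).
#' @param digits Digits for rounding the percent (default 0, the convention
#'   of clinical effect tables).
#' @return Character vector like `"23% decrease"`.
#' @export
#' @examples
#' render_hazard_difference(0.77)
#' render_hazard_difference(1)
render_hazard_difference <- function(hr, digits = 0) {
  pct <- (hr - 1) * 100
  ifelse(pct == 0, "0% change",
         paste0(formatC(abs(pct), format = "f", digits = digits), "% ",
                ifelse(pct > 0, "increase", "decrease")))
}

#' @export
print.ohd_cox <- function(x, ...) {
  cat("<ohd_cox> ", x$mode, " proportional-hazards fit: ", x$n, " records, ",
      x$n_events, " failures\n", sep = "")
  print(x$table |> dplyr::select(dplyr::all_of(c("term", "p", "label"))))
  invisible(x)
}

#' Kernel-smoothed hazard-rate curve
#'
#' Smooths the Nelson-Aalen hazard increments with an Epanechnikov kernel on
#' a uniform time grid, renormalizing the kernel mass near the boundaries of
#' the observed follow-up range.
#'
#' @param events Event table (needs >= 1 failure).
#' @param bandwidth Kernel bandwidth in years (> 0, default 1).
#' @param grid_length Number of grid points (default 101).
#' @return An object of class `ohd_hazard`: tibble `curve` with `time` and
#'   `hazard`, plus `bandwidth`.
#' @export
hazard_rate <- function(events, bandwidth = 1, grid_length = 101L) {
  if (!is.finite(bandwidth) || bandwidth <= 0) stop("bandwidth must be positive")
  if (sum(events$event) < 1L) stop("at least one failure is required")
  time <- events$time_years; status <- events$event
  ut <- sort(unique(time[status == 1L]))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & status == 1L), 0)
  dA <- n_event / n_risk
  tmax <- max(time)
  grid <- seq(0, tmax, length.out = grid_length)
  epan <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)
  hz <- vapply(grid, function(g) {
    w <- epan((g - ut) / bandwidth) / bandwidth
    # boundary renormalization: divide by the kernel mass inside [0, tmax]
    lo <- max(-1, (g - tmax) / bandwidth); hi <- min(1, g / bandwidth)
    mass <- max(0.75 * (hi - hi^3 / 3) - 0.75 * (lo - lo^3 / 3), 1e-12)
    sum(w * dA) / mass
  }, 0)
  structure(list(curve = tibble::tibble(time = grid, hazard = hz),
                 bandwidth = bandwidth),
            class = "ohd_hazard")
}

#' Mean smoothed hazard over an interval
#'
#' @param hz An `ohd_hazard`.
#' @param from,to Interval bounds in years (`(from, to]`).
#' @return Mean of the smoothed hazard at grid points inside the interval.
#' @export
mean_hazard <- function(hz, from, to) {
  cv <- hz$curve
  sel <- cv$time > from & cv$time <= to
  if (!any(sel)) return(NA_real_)
  mean(cv$hazard[sel])
}

#' Event-count breakdown by correlate
#'
#' One row per level of each correlate with the number of distinct patients,
#' the number of events (failures plus censored) and the number of failures —
#' the standard cohort-description table of a restoration-longevity analysis.
#'
#' @param events Event table with the `patient` column retained.
#' @return A tibble with columns `correlate`, `group`, `n_patients`,
#'   `n_events`, `n_failures`.
#' @export
summarize_by_correlate <- function(events) {
  lv <- list(
    gender = function(e) ifelse(e$gender == "female", "Gender female", "Gender male"),
    tooth = function(e) ifelse(e$posterior, "Posterior tooth", "Anterior tooth"),
    age = function(e) ifelse(e$age_ge_40, "Age 40 and over", "Age under 40"),
    surfaces = function(e) ifelse(e$multisurface, "Multiple surface", "Single surface"))
  dplyr::bind_rows(lapply(names(lv), function(nm) {
    events |>
      dplyr::mutate(group = lv[[nm]](events), correlate = nm) |>
      dplyr::group_by(.data$correlate, .data$group) |>
      dplyr::summarise(n_patients = dplyr::n_distinct(.data$patient),
                       n_events = dplyr::n(),
                       n_failures = sum(.data$event), .groups = "drop")
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
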