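# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname km_fit
#' @param x An `ohd_km`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ohd_km <- function(x, ...) x$curve

#' @rdname km_fit
#' @exportS3Method generics::glance
glance.ohd_km <- function(x, ...) {
  x$medians |>
    dplyr::summarise(n = sum(.data$n), events = sum(.data$events),
                     n_groups = dplyr::n(),
                     median = .data$median[1])
}

#' @rdname cox_fit
#' @param x An `ohd_cox`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ohd_cox <- function(x, ...) {
  x$table |>
    dplyr::select(term = "term", estimate = "beta", std.error = "se",
                  p.value = "p", hr = "hr", conf.low = "hr_lower",
                  conf.high = "hr_upper", label = "label")
}

#' @rdname cox_fit
#' @exportS3Method generics::glance
glance.ohd_cox <- function(x, ...) {
  fit <- x$fits[[1]]
  tibble::tibble(n = x$n, n_events = x$n_events, mode = x$mode,
                 concordance = unname(summary(fit)$concordance[1]))
}

#' @rdname hazard_rate
#' @param x An `ohd_hazard`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ohd_hazard <- function(x, ...) x$curve

#' Plot a Kaplan-Meier fit
#'
#' Step curves with shaded pointwise confidence bands, one colour per group.
#'
#' @param object An `ohd_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ohd_km <- function(object, ...) {
  stepped <- object$curve |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, ...) {
      d <- dplyr::bind_rows(
        tibble::tibble(time = 0, surv = 1, lower = 1, upper = 1), d)
      n <- nrow(d)
      tibble::tibble(
        time = rep(d$time, each = 2)[-1],
        surv = rep(d$surv, each = 2)[-2 * n],
        lower = rep(d$lower, each = 2)[-2 * n],
        upper = rep(d$upper, each = 2)[-2 * n])
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(stepped, ggplot2::aes(x = .data$time, y = .data$surv,
                                        colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since restoration", y = "Survival probability",
                  colour = object$group_by, fill = object$group_by) +
    ggplot2::theme_minimal()
}

#' Plot a smoothed hazard-rate curve
#'
#' @param object An `ohd_hazard`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ohd_hazard <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$time, y = .data$hazard)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Years since restoration", y = "Hazard rate (1/year)",
                  subtitle = paste0("Epanechnikov kernel, bandwidth ",
                                    object$bandwidth, " y")) +
    ggplot2::theme_minimal()
}

#' Plot Cox effects as percent hazard change
#'
#' @param object An `ohd_cox`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ohd_cox <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pct_change, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = (.data$hr_lower - 1) * 100,
                                         xmax = (.data$hr_upper - 1) * 100),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Hazard change (%)", y = NULL) +
    ggplot2::theme_minimal()
}
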