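#' Tidy a propagation fit
#'
#' @param x A [fit_propagation()] result.
#' @param model Which parameterization: `"log_distance"` (default) or
#'   `"linear_distance"`; `"both"` returns the stacked table.
#' @param ... Unused.
#' @return A tibble of coefficients with standard errors, Satterthwaite
#'   df, t statistics and p-values.
#' @exportS3Method generics::tidy
tidy.propagation_fit <- function(x, model = c("log_distance",
                                              "linear_distance", "both"),
                                 ...) {
  model <- match.arg(model)
  if (model == "both") return(x$coefficients)
  x$coefficients[x$coefficients$model == model, , drop = FALSE]
}

#' @rdname tidy.propagation_fit
#' @param x A [fit_propagation()] result.
#' @return `glance()`: a one-row tibble with the estimated slope and SE,
#'   residual and pair-level SDs, observations used and censored bins
#'   dropped.
#' @exportS3Method generics::glance
glance.propagation_fit <- function(x, ...) {
  sl <- x$coefficients[x$coefficients$model == "log_distance" &
                         x$coefficients$term == "log_eff_d", ]
  tibble::tibble(
    slope_per_log10m = sl$estimate,
    slope_se = sl$std_error,
    sigma = x$varcomp$sd[x$varcomp$group == "Residual"],
    pair_sd = x$varcomp$sd[x$varcomp$group == "pair_id"][1],
    n_obs = x$n_used,
    n_censored = x$n_censored,
    n_bins_dropped = length(x$dropped_bins)
  )
}

#' Tidy a dyadic-probability fit
#'
#' @param x A [fit_dyad_probability()] result.
#' @param ... Unused.
#' @return Coefficient tibble with Wald z statistics.
#' @exportS3Method generics::tidy
tidy.dyad_prob_fit <- function(x, ...) x$coefficients

#' @rdname tidy.dyad_prob_fit
#' @exportS3Method generics::glance
glance.dyad_prob_fit <- function(x, ...) {
  f <- x$glm_fit
  tibble::tibble(
    n = x$n,
    n_dyadic = x$n_dyadic,
    null_deviance = f$null.deviance,
    deviance = f$deviance,
    aic = f$aic,
    separated = x$separated
  )
}

#' Plot a propagation fit
#'
#' Calibration readings by distance and orientation with the fitted (and,
#' when supplied, the generating) expected-RSSI curves overlaid.
#'
#' @param object A [fit_propagation()] result.
#' @param records Calibration tibble to show as points (optional).
#' @param true_params Optional [propagation_params()] used to generate the
#'   data, drawn dashed.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.propagation_fit <- function(object, records = NULL,
                                     true_params = NULL, ...) {
  p_est <- object$params
  grid <- tidyr::expand_grid(
    distance_m = exp(seq(log(p_est$d_min_clamp), log(15), length.out = 120)),
    orientation = c("parallel", "perpendicular")
  ) |>
    dplyr::mutate(
      theta = ifelse(.data$orientation == "perpendicular", pi / 2, 0),
      fitted = expected_rssi(.data$distance_m, .data$theta, "body", p_est)
    )
  gg <- ggplot2::ggplot(grid,
    ggplot2::aes(.data$distance_m, .data$fitted,
                 colour = .data$orientation)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance (m)", y = "RSSI", colour = "orientation")
  if (!is.null(true_params)) {
    grid$truth <- expected_rssi(grid$distance_m, grid$theta, "body",
                                true_params)
    gg <- gg + ggplot2::geom_line(
      ggplot2::aes(y = .data$truth), data = grid, linetype = "dashed")
  }
  if (!is.null(records)) {
    gg <- gg + ggplot2::geom_jitter(
      data = records,
      ggplot2::aes(pmax(.data$distance_m, p_est$d_min_clamp), .data$rssi,
                   colour = .data$orientation),
      width = 0.02, alpha = 0.3, size = 0.8, inherit.aes = FALSE)
  }
  gg
}
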