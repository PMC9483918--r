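# ggplot2 views of the result types.

#' Plot a density profile
#' @param object a `density_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$z, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)",
                  y = expression(rho ~ (nm^-3)),
                  title = attr(object, "selection_label")) +
    ggplot2::theme_minimal()
}

#' Plot a PMF profile
#' @param object a `pmf_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pmf_profile
#' @export
autoplot.pmf_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(as_tibble(object), !is.na(.data$pmf)),
                  ggplot2::aes(.data$z, .data$pmf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "PMF (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a bound-count time series
#' @param object a `bound_series`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot bound_series
#' @export
autoplot.bound_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time / 1000, .data$n_bound)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ns)", y = "bound molecules") +
    ggplot2::theme_minimal()
}

#' Plot a criterion surface
#' @param object a `criterion_surface`.
#' @param ... unused.
#' @return A ggplot (tile map of the time-averaged bound count).
#' @method autoplot criterion_surface
#' @export
autoplot.criterion_surface <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$distance_cutoff, .data$bound_fraction,
                               fill = .data$n_bound_mean)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "distance cutoff (nm)", y = "bound-atom fraction",
                  fill = "<n bound>") +
    ggplot2::theme_minimal()
}

#' Plot a response curve
#' @param object a `response_curve`.
#' @param ... unused.
#' @return A ggplot with the through-origin fit line.
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  slope <- fit_response_slope(object)$slope
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$x, .data$delta_s)) +
    ggplot2::geom_abline(slope = slope, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$delta_s - .data$stderr,
      ymax = .data$delta_s + .data$stderr)) +
    ggplot2::labs(x = object$x_kind[1], y = expression(Delta * S[CH]),
                  title = object$label[1]) +
    ggplot2::theme_minimal()
}
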