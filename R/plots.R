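#' Plot a swelling solution
#'
#' Swelling-degree curve `Q(t)` with the front-radius ratio as a secondary
#' panel caption.
#'
#' @param object A `swelling_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swelling_solution <- function(object, ...) {
  df <- swelling_degree_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 60,
                                   y = .data$swelling_degree)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "time [min]", y = "swelling degree Q(t) [g/g]",
      title = sprintf("%s in %s", object$formulation$name,
                      object$medium$name),
      subtitle = sprintf("final diameter ratio %.2f",
                         df$front_radius_m[nrow(df)] / df$front_radius_m[1])) +
    ggplot2::theme_minimal()
}

#' Plot a release solution
#'
#' Differential (reservoir concentration, sawtooth) and integral
#' (withdrawal-corrected cumulative fraction) release curves.
#'
#' @param object A `release_solution`.
#' @param which `"both"`, `"differential"`, or `"integral"`.
#' @param ... Unused.
#' @return A ggplot object (patchworked side by side for `"both"`).
#' @export
autoplot.release_solution <- function(object,
                                      which = c("both", "differential",
                                                "integral"), ...) {
  which <- match.arg(which)
  cv <- object$curve
  p_diff <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$time_min,
                                             y = .data$C_res)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(data = object$ledger,
                        ggplot2::aes(x = .data$t_w_min, y = .data$C_w),
                        size = 1.6, colour = "firebrick") +
    ggplot2::labs(x = "time [min]", y = "C_res [mg/mL]") +
    ggplot2::theme_minimal()
  p_int <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$time_min,
                                            y = .data$released_fraction)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "time [min]", y = "fraction released") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  switch(which, differential = p_diff, integral = p_int,
         both = patchwork::wrap_plots(p_diff, p_int, ncol = 2))
}

#' Plot fit residuals and data overlay
#'
#' @param object A `gelbead_fit`.
#' @param ... Unused.
#' @return A ggplot object of residuals against time.
#' @export
autoplot.gelbead_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$time_min, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::labs(x = "time [min]", y = "residual (data units)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
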