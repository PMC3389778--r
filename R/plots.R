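#' Plot a simulation result
#'
#' Stacked panels of membrane potential, cytosolic and averaged subspace
#' Ca2+, and normalised force against time.
#'
#' @param object a `gp_result`.
#' @param vars columns to plot (default a standard set).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gp_result <- function(object, vars = c("V", "cai", "ca_ss_avg",
                                                "force_norm"), ...) {
  vars <- intersect(vars, names(object))
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "time", dplyr::all_of(vars)),
    -"time", names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL)
}

#' Plot an ECC gain curve
#'
#' Normalised peak LCC and RyR fluxes and the gain against test potential.
#'
#' @param object a `gp_gain_curve` from [ecc_gain_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gp_gain_curve <- function(object, ...) {
  df <- tibble(
    test = rep(object$test, 2),
    value = c(object$j_lcc_peak / max(object$j_lcc_peak),
              object$j_ryr_peak / max(object$j_ryr_peak)),
    flux = rep(c("LCC (normalised)", "RyR (normalised)"),
               each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$test, .data$value,
                                   colour = .data$flux)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "test potential (mV)", y = "normalised peak flux",
                  colour = NULL)
}

#' Plot a restitution curve with its exponential fit
#'
#' @param data tibble with `di` and `apd` (from [run_s1s2_restitution()]).
#' @param fit optional `gp_expfit` to overlay.
#' @return a ggplot object.
#' @export
plot_restitution <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$di, .data$apd)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "diastolic interval (ms)", y = "APD90 (ms)")
  if (!is.null(fit)) {
    cf <- coef(fit$fit)
    grid <- tibble(di = seq(min(data$di, na.rm = TRUE),
                            max(data$di, na.rm = TRUE), length.out = 200))
    grid$apd <- cf[["offset"]] - cf[["amplitude"]] * exp(-grid$di / cf[["tau"]])
    p <- p + ggplot2::geom_line(data = grid, colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
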