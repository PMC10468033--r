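#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the package's result tibbles: relaxation
#' time-constant profiles (log10 ms over mV), I-V scans (normalized current,
#' steady-state versus all-ODE), simulation traces (Vm, Ca2+ and force
#' stacked over time) and candidate reports (tau maxima against the
#' time-scale threshold).
#'
#' @param object A `tau_profile`, `iv_curve`, `sim_trace` or
#'   `candidate_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_methods
NULL

#' @rdname autoplot_methods
#' @method autoplot tau_profile
#' @export
autoplot.tau_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$Vm_mV, .data$tau_ms,
                                       colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Vm (mV)", y = expression(tau ~ "(ms)"),
                  colour = "variable") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @method autoplot iv_curve
#' @export
autoplot.iv_curve <- function(object, ...) {
  modes <- attr(object, "modes")
  lab <- paste(names(modes)[modes == "SS"], collapse = "+")
  if (lab == "") lab <- "all-ODE"
  else lab <- paste0(lab, " SS")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("I_norm", "I_norm_ode"),
                              names_to = "curve", values_to = "I")
  long$curve <- ifelse(long$curve == "I_norm_ode", "all-ODE", lab)
  ggplot2::ggplot(long, ggplot2::aes(.data$Vm_mV, .data$I,
                                     colour = .data$curve,
                                     linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Vm (mV)", y = "normalized current",
                  title = sprintf("%s, T = %g ms", attr(object, "channel"),
                                  attr(object, "horizon_T_ms")),
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @method autoplot sim_trace
#' @export
autoplot.sim_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_ms", "Vm_mV", "Ca_nM", "force")],
    -"time_ms", names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal, levels = c("Ca_nM", "Vm_mV", "force"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms / 1000, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @method autoplot candidate_report
#' @export
autoplot.candidate_report <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$max_tau_ms))
  ggplot2::ggplot(dat, ggplot2::aes(stats::reorder(.data$variable,
                                                   .data$max_tau_ms),
                                    .data$max_tau_ms,
                                    fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = dat$threshold_ms[1], linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(max ~ tau ~ "(ms)"),
                  fill = "SS candidate") +
    ggplot2::theme_minimal()
}
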