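#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarise result objects
#'
#' broom-style accessors: `tidy()` returns the observation-level tibble
#' (long signals for traces, one row per variable for candidate reports,
#' one row per grid point for I-V curves); `glance()` returns a one-row
#' summary (trace extrema; per-signal maxima for comparisons collapsed to
#' one row; scan deviation summary).
#'
#' @param x A `sim_trace`, `candidate_report`, `iv_curve` or
#'   `trace_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @name broom_methods
NULL

#' @rdname broom_methods
#' @method tidy sim_trace
#' @export
tidy.sim_trace <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("time_ms", "Vm_mV", "Ca_nM", "force")],
    -"time_ms", names_to = "signal", values_to = "value")
}

#' @rdname broom_methods
#' @method glance sim_trace
#' @export
glance.sim_trace <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    t_max_s = max(x$time_ms) / 1000,
    Vm_rest_mV = x$Vm_mV[1],
    Vm_peak_mV = max(x$Vm_mV),
    Ca_min_nM = min(x$Ca_nM),
    Ca_peak_nM = max(x$Ca_nM),
    force_peak = max(x$force)
  )
}

#' @rdname broom_methods
#' @method tidy candidate_report
#' @export
tidy.candidate_report <- function(x, ...) tibble::as_tibble(x)

#' @rdname broom_methods
#' @method glance candidate_report
#' @export
glance.candidate_report <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x),
    n_candidates = sum(x$flagged, na.rm = TRUE),
    n_unknown = sum(is.na(x$flagged)),
    threshold_ms = x$threshold_ms[1],
    T_interest_s = attr(x, "T_interest_s")
  )
}

#' @rdname broom_methods
#' @method tidy iv_curve
#' @export
tidy.iv_curve <- function(x, ...) tibble::as_tibble(x)

#' @rdname broom_methods
#' @method glance iv_curve
#' @export
glance.iv_curve <- function(x, ...) {
  tibble::tibble(
    channel = attr(x, "channel"),
    horizon_T_ms = attr(x, "horizon_T_ms"),
    holding_Vm = attr(x, "holding_Vm"),
    normalizer_pA_pF = attr(x, "normalizer"),
    max_abs_dI = iv_deviation(x)
  )
}

#' @rdname broom_methods
#' @method glance trace_comparison
#' @export
glance.trace_comparison <- function(x, ...) {
  m <- attr(x, "maxima")
  out <- tidyr::pivot_wider(m, names_from = "signal",
                            values_from = "max_rel_diff",
                            names_prefix = "max_rel_diff_")
  out$metric <- attr(x, "metric")
  out
}
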