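#' Flag steady-state approximation candidates by relaxation time scale
#'
#' Implements the time-scale rule of thumb: a gating variable is a candidate
#' for steady-state substitution when its maximum relaxation time constant
#' over the voltage span of interest does not exceed `threshold_fraction`
#' times the time scale of interest, `tau_max <= threshold_fraction * T_i`.
#' Variables whose time-constant expressions are not available (declared-only
#' channels) are reported with status `"unknown"`, never silently flagged.
#' The rule is a screen, not a verdict: variables failing it can still be
#' substituted successfully when their tau peak sits outside the voltages
#' visited during simulation (see [verify_candidate()]).
#'
#' @param cfg A [model_config()].
#' @param T_interest Time scale of interest, seconds.
#' @param V_span Length-2 voltage span of interest, mV.
#' @param threshold_fraction Fraction of `T_interest` (default 0.01).
#' @param Ca Reference Ca2+ (nM), unused by tau but recorded.
#'
#' @return A tibble of class `candidate_report` with columns `variable`,
#'   `channel`, `role`, `max_tau_ms`, `threshold_ms`, `flagged` (logical,
#'   `NA` for unknown) and `status`.
#' @examples
#' identify_ss_candidates(preset_demo(), T_interest = 1, V_span = c(-50, 50))
#' @export
identify_ss_candidates <- function(cfg, T_interest, V_span = c(-50, 50),
                                   threshold_fraction = 0.01, Ca = NULL) {
  stopifnot(inherits(cfg, "model_config"), T_interest > 0,
            length(V_span) == 2)
  V_span <- sort(as.numeric(V_span))
  threshold_ms <- threshold_fraction * T_interest * 1000
  grid <- voltage_grid(V_span[1], V_span[2], step = 1)
  gates <- enabled_gates(cfg)
  gates <- purrr::keep(gates, function(g) g$mode == "ODE")
  rows <- purrr::map(gates, function(g) {
    if (g$stub) {
      tibble::tibble(variable = g$name, channel = g$channel, role = g$role,
                     max_tau_ms = NA_real_, threshold_ms = threshold_ms,
                     flagged = NA, status = "unknown")
    } else {
      mt <- max_tau(tau_profile(g, grid), V_span)
      tibble::tibble(variable = g$name, channel = g$channel, role = g$role,
                     max_tau_ms = mt, threshold_ms = threshold_ms,
                     flagged = mt <= threshold_ms,
                     status = if (mt <= threshold_ms) "candidate" else "retain")
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("candidate_report", class(out))
  attr(out, "T_interest_s") <- T_interest
  attr(out, "V_span") <- V_span
  attr(out, "threshold_fraction") <- threshold_fraction
  out
}

#' Verify a steady-state candidate against clamped-voltage scans
#'
#' Evidence-based check complementing the time-scale rule: substitute one
#' variable (or several) with its steady state in the channel's I-V scan and
#' report the maximum normalized current deviation from the all-ODE scan at
#' each horizon.
#'
#' @param ch A [channel()].
#' @param variable Gate name(s) to substitute.
#' @param grid A [voltage_grid()] (default \[-100, 60\] mV).
#' @param horizons Scan horizons, ms.
#' @param holding_Vm Holding potential, mV.
#' @param Ca Fixed Ca2+ for Ca2+-modulated gating, nM.
#'
#' @return A tibble with columns `channel`, `variables`, `horizon_ms`,
#'   `max_abs_dI` (normalized).
#' @examples
#' verify_candidate(chan_cat(), "b", horizons = c(10, 100))
#' @export
verify_candidate <- function(ch, variable, grid = voltage_grid(-100, 60),
                             horizons = c(10, 100), holding_Vm = -55,
                             Ca = NULL) {
  stopifnot(inherits(ch, "channel"))
  bad <- setdiff(variable, names(ch$gates))
  if (length(bad)) {
    stop(sprintf("variable(s) %s do not belong to channel '%s'",
                 paste(bad, collapse = ", "), ch$id), call. = FALSE)
  }
  modes <- stats::setNames(rep("SS", length(variable)), variable)
  purrr::map_dfr(horizons, function(Tm) {
    curve <- iv_scan(ch, grid, horizon_T = Tm, holding_Vm = holding_Vm,
                     modes = modes, Ca = Ca)
    tibble::tibble(channel = ch$id,
                   variables = paste(variable, collapse = "+"),
                   horizon_ms = Tm, max_abs_dI = iv_deviation(curve))
  })
}

#' Compare a reduced trace against a reference trace
#'
#' Pointwise range-normalized difference per signal:
#' `|x_red(t) - x_ref(t)| / (max_t x_ref - min_t x_ref)` for `Vm`, `Ca` and
#' force on the common uniform time grid (well-defined for signals crossing
#' zero). The normalization choice is recorded in the report's metadata.
#'
#' @param ref,red `sim_trace` objects sharing protocol and time grid.
#' @return A long tibble of class `trace_comparison` with columns `time_ms`,
#'   `signal`, `rel_diff`; the per-signal maxima are available via
#'   [glance()] and the `maxima` attribute.
#' @export
compare_traces <- function(ref, red) {
  stopifnot(inherits(ref, "sim_trace"), inherits(red, "sim_trace"))
  pref <- attr(ref, "metadata")$protocol
  pred <- attr(red, "metadata")$protocol
  same_prot <- isTRUE(all.equal(pref[c("amplitude", "onset", "duration", "t_max")],
                                pred[c("amplitude", "onset", "duration", "t_max")]))
  if (!same_prot) stop("traces were produced under different protocols",
                       call. = FALSE)
  if (nrow(ref) != nrow(red) || any(ref$time_ms != red$time_ms)) {
    stop("traces are not on the same time grid", call. = FALSE)
  }
  signals <- c(Vm = "Vm_mV", Ca = "Ca_nM", force = "force")
  long <- purrr::imap_dfr(signals, function(col, nm) {
    x_ref <- ref[[col]]
    x_red <- red[[col]]
    rng <- max(x_ref) - min(x_ref)
    denom <- if (rng > 0) rng else 1
    tibble::tibble(time_ms = ref$time_ms, signal = nm,
                   rel_diff = abs(x_red - x_ref) / denom)
  })
  maxima <- long |>
    dplyr::group_by(.data$signal) |>
    dplyr::summarise(max_rel_diff = max(.data$rel_diff), .groups = "drop")
  class(long) <- c("trace_comparison", class(long))
  attr(long, "maxima") <- maxima
  attr(long, "metric") <- "pointwise |red - ref| / range(ref)"
  attr(long, "ref_hash") <- attr(ref, "metadata")$config_hash
  attr(long, "red_hash") <- attr(red, "metadata")$config_hash
  long
}

#' Rank channel conductances
#'
#' Orders enabled channels by maximal conductance (descending; ties broken
#' lexicographically by id for determinism) and computes each channel's
#' share of its ion-class total — the first step of representative-channel
#' elimination.
#'
#' @param cfg A [model_config()].
#' @return A tibble of class `conductance_ranking` with columns `channel`,
#'   `ion_class`, `gbar_nS_pF`, `class_share`.
#' @examples
#' rank_conductances(preset_ftm("published"))
#' @export
rank_conductances <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  classes <- stats::setNames(source_conductances()$ion_class,
                             source_conductances()$channel)
  chans <- purrr::keep(cfg$channels, "enabled")
  out <- tibble::tibble(
    channel = unname(purrr::map_chr(chans, "id")),
    ion_class = unname(dplyr::coalesce(
      classes[purrr::map_chr(chans, "id")],
      purrr::map_chr(chans, function(ch) {
        ifelse(is.na(ch$reversal$ion), "other", ch$reversal$ion)
      }))),
    gbar_nS_pF = unname(purrr::map_dbl(chans, "gbar"))
  ) |>
    dplyr::group_by(.data$ion_class) |>
    dplyr::mutate(class_share = if (sum(.data$gbar_nS_pF) > 0)
      .data$gbar_nS_pF / sum(.data$gbar_nS_pF) else NA_real_) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$gbar_nS_pF), .data$channel)
  class(out) <- c("conductance_ranking", class(out))
  out
}

#' Apply a reduction plan to a configuration
#'
#' A plan disables channels (conductance-based elimination), switches gating
#' variables to steady-state mode (time-scale-based reduction) and applies
#' conductance/buffering overrides. Returns a new configuration; the input
#' is not modified. Disabling a channel and steady-state-switching one of
#' its variables in the same plan is a conflict.
#'
#' @param cfg A [model_config()].
#' @param plan List with optional elements `disable` (channel ids), `ss`
#'   (gating variable names) and `overrides` (list with named numeric `gbar`
#'   and/or scalar `beta`).
#'
#' @return A new [model_config()].
#' @examples
#' plan <- list(disable = c("K2", "Ka", "h"),
#'              ss = c("x_alpha", "x_beta", "b", "g", "d", "f1", "m", "h"))
#' count_gating_odes(apply_reduction(preset_ftm(), plan))
#' @export
apply_reduction <- function(cfg, plan = list()) {
  stopifnot(inherits(cfg, "model_config"), is.list(plan))
  allowed <- c("disable", "ss", "exchangers_off", "overrides")
  unknown <- setdiff(names(plan), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown plan element(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  out <- cfg
  disable <- plan$disable %||% character(0)
  ss <- plan$ss %||% character(0)

  bad <- setdiff(disable, names(out$channels))
  if (length(bad)) {
    stop(sprintf("unknown channel id(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(names(out$channels), collapse = ", ")), call. = FALSE)
  }
  all_gates <- unlist(purrr::map(out$channels, function(ch) names(ch$gates)))
  bad <- setdiff(ss, all_gates)
  if (length(bad)) {
    stop(sprintf("unknown gating variable(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(all_gates, collapse = ", ")), call. = FALSE)
  }
  for (id in disable) {
    conflict <- intersect(ss, names(out$channels[[id]]$gates))
    if (length(conflict)) {
      stop(sprintf("plan disables channel '%s' and SS-switches its variable(s) %s",
                   id, paste(conflict, collapse = ", ")), call. = FALSE)
    }
  }

  for (id in disable) out$channels[[id]]$enabled <- FALSE
  out$modes[ss] <- "SS"
  for (ex in plan$exchangers_off %||% character(0)) {
    if (!ex %in% names(out$exchangers)) {
      stop(sprintf("unknown exchanger '%s' (valid: %s)", ex,
                   paste(names(out$exchangers), collapse = ", ")),
           call. = FALSE)
    }
    out$exchangers[[ex]] <- FALSE
  }
  ov <- plan$overrides %||% list()
  if (!is.null(ov$gbar)) {
    bad <- setdiff(names(ov$gbar), names(out$channels))
    if (length(bad)) {
      stop(sprintf("gbar override for unknown channel(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (id in names(ov$gbar)) out$channels[[id]]$gbar <- ov$gbar[[id]]
  }
  if (!is.null(ov$beta)) {
    if (ov$beta <= 0 || ov$beta > 1) stop("`beta` override must be in (0, 1]",
                                          call. = FALSE)
    out$beta <- ov$beta
  }
  out
}
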