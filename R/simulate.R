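#' Stimulus protocols
#'
#' A rectangular applied-current pulse: `amplitude` pA/pF from `onset` for
#' `duration` seconds, simulated out to `t_max` seconds. `ssp()` is the
#' standard simulation protocol used throughout: -0.5 pA/pF for 2 s
#' (negative applied current depolarises under the sign convention of
#' [cell_rhs()]), onset 1 s, horizon 10 s.
#'
#' @param amplitude Applied current, pA/pF.
#' @param onset Stimulus onset, s.
#' @param duration Stimulus duration, s (>= 0).
#' @param t_max Simulation horizon, s (>= onset + duration).
#' @param initial_Ko Optional elevated extracellular K+ (mM) applied as a
#'   fixed value for the whole run (the K+-pulse variant); reversal
#'   potentials of K+-selective channels are recomputed by Nernst.
#'
#' @return An object of class `stimulus_protocol`.
#' @examples
#' ssp()
#' @export
protocol <- function(amplitude, onset = 1, duration, t_max,
                     initial_Ko = NULL) {
  if (duration < 0) stop("`duration` must be >= 0", call. = FALSE)
  if (onset + duration > t_max) {
    stop("`onset + duration` must be <= `t_max`", call. = FALSE)
  }
  structure(list(amplitude = amplitude, onset = onset, duration = duration,
                 t_max = t_max, initial_Ko = initial_Ko),
            class = "stimulus_protocol")
}

#' @rdname protocol
#' @export
ssp <- function() protocol(amplitude = -0.5, onset = 1, duration = 2,
                           t_max = 10)

#' @rdname protocol
#' @param prot A `stimulus_protocol`.
#' @param t_ms Time(s) in ms.
#' @return `stimulus_at()`: applied current (pA/pF) at `t_ms`.
#' @export
stimulus_at <- function(prot, t_ms) {
  stopifnot(inherits(prot, "stimulus_protocol"))
  on <- prot$onset * 1000
  off <- (prot$onset + prot$duration) * 1000
  ifelse(t_ms >= on & t_ms < off, prot$amplitude, 0)
}

#' Stiff-solver settings
#'
#' Defaults follow the reference numerical setup: a backward-differentiation
#' (BDF) multistep method with absolute and relative tolerances of 1e-7 and
#' a maximum adaptive step of 0.1 ms.
#'
#' @param method deSolve method name (default `"bdf"`).
#' @param abs_tol,rel_tol Solver tolerances (> 0).
#' @param max_step Maximum step size, ms (> 0).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(method = "bdf", abs_tol = 1e-7, rel_tol = 1e-7,
                            max_step = 0.1) {
  if (abs_tol <= 0 || rel_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (max_step <= 0) stop("`max_step` must be > 0", call. = FALSE)
  structure(list(method = method, abs_tol = abs_tol, rel_tol = rel_tol,
                 max_step = max_step),
            class = "solver_settings")
}

# Apply a fixed elevated extracellular K+ to every K+-selective reversal.
apply_ko_override <- function(cfg, Ko) {
  Ki <- cfg$fixed_ions$K_i
  EK <- nernst(reversal_nernst(Ko, Ki, valence = 1L))
  for (id in names(cfg$channels)) {
    rp <- cfg$channels[[id]]$reversal
    if (identical(rp$ion, "K") && rp$mode == "fixed") {
      cfg$channels[[id]]$reversal$value <- EK
    }
  }
  cfg
}

# Hash of the parts of a config that determine the solution.
config_hash <- function(cfg) {
  en <- purrr::map_lgl(cfg$channels, "enabled")
  rlang::hash(list(
    variant = cfg$variant,
    gbar = purrr::map_dbl(cfg$channels, "gbar"),
    enabled = en,
    beta = cfg$beta, flux_conversion = cfg$flux_conversion,
    ca_clearance = cfg$ca_clearance, exchangers = cfg$exchangers,
    modes = cfg$modes, force = cfg$force_params
  ))
}

#' Simulate a whole-cell configuration under a stimulus protocol
#'
#' Integrates the model with a stiff BDF solver and returns the trace
#' resampled on a uniform 1 ms grid, with per-channel currents recomputed at
#' each output point.
#'
#' @param cfg A [model_config()] whose channels are all simulatable.
#' @param prot A [protocol()] (default [ssp()]).
#' @param solver [solver_settings()].
#' @param init Optional [cell_state()]; defaults to the config's
#'   `initial_state`, else [resting_state()].
#' @param out_dt Output sampling interval, ms.
#'
#' @return A tibble of class `sim_trace` with columns `time_ms`, `Vm_mV`,
#'   `Ca_nM`, `force`, `Iapp` and one `I_<id>` column per enabled channel,
#'   plus `metadata` attribute (config hash, protocol, solver).
#' @examples
#' \donttest{
#' demo <- preset_demo()
#' tr <- simulate_cell(demo, protocol(0, duration = 0, t_max = 1))
#' }
#' @export
simulate_cell <- function(cfg, prot = ssp(), solver = solver_settings(),
                          init = NULL, out_dt = 1) {
  stopifnot(inherits(cfg, "model_config"),
            inherits(prot, "stimulus_protocol"),
            inherits(solver, "solver_settings"))
  if (!is.null(prot$initial_Ko)) cfg <- apply_ko_override(cfg, prot$initial_Ko)
  gates <- enabled_gates(cfg)
  fast <- make_fast_rhs(cfg)
  ode_names <- fast$ode_names
  if (is.null(init)) init <- cfg$initial_state
  if (is.null(init)) init <- resting_state(cfg)
  y0 <- c(Vm = init$Vm, Ca = init$Ca, omega = init$omega,
          init$gating[ode_names])
  times <- seq(0, prot$t_max * 1000, by = out_dt)

  on_ms <- prot$onset * 1000
  off_ms <- (prot$onset + prot$duration) * 1000
  amp <- prot$amplitude
  func <- function(t, y, parms) {
    iapp <- if (t >= on_ms && t < off_ms) amp else 0
    list(fast$derivs(t, y, iapp))
  }

  sol <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = solver$method, atol = solver$abs_tol,
                      rtol = solver$rel_tol, hmax = solver$max_step)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("integration failed at t = %g ms (last good state Vm = %g)",
                 max(sol[, "time"]), sol[nrow(sol), "Vm"]), call. = FALSE)
  }
  sol <- as.data.frame(sol)
  if (any(!is.finite(sol$Vm)) || any(sol$Ca <= 0)) {
    stop("trace contains non-finite Vm or non-positive Ca", call. = FALSE)
  }

  currents <- purrr::map(seq_len(nrow(sol)), function(i) {
    gv_ode <- stats::setNames(as.numeric(sol[i, ode_names, drop = TRUE]),
                              ode_names)
    gv <- resolve_gating(gates, pmin(pmax(gv_ode, 0), 1),
                         sol$Vm[i], sol$Ca[i])
    fast$currents(gv, sol$Vm[i], sol$Ca[i])
  })
  Imat <- do.call(rbind, currents)
  colnames(Imat) <- paste0("I_", colnames(Imat))

  out <- tibble::as_tibble(cbind(
    data.frame(time_ms = sol$time, Vm_mV = sol$Vm, Ca_nM = sol$Ca,
               force = sol$omega, Iapp = stimulus_at(prot, sol$time)),
    as.data.frame(Imat)
  ))
  gating_cols <- tibble::as_tibble(sol[, ode_names, drop = FALSE])
  out <- dplyr::bind_cols(out, gating_cols)
  class(out) <- c("sim_trace", class(out))
  attr(out, "metadata") <- list(
    config_hash = config_hash(cfg), variant = cfg$variant,
    protocol = unclass(prot), solver = unclass(solver),
    fixed_Ko = prot$initial_Ko, ode_gating = ode_names
  )
  out
}
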