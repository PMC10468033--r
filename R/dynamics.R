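#' Contractile force submodel
#'
#' Force activation follows first-order kinetics toward a Hill-type
#' steady-state in free Ca2+:
#' `omega_ss = 1 / (1 + (K_mF / Ca)^n_F)` with half-maximal activation at
#' `K_mF` (about 160 nM) and Hill coefficient `n_F` (about 3.6), and
#' `tau_omega = 4000 * (0.235 + (1 - 0.235) / (1 + (Ca / K_mF)^n_F))` ms,
#' i.e. 4 s at low Ca2+ falling to 940 ms at saturating Ca2+.
#'
#' @param Ca Free intracellular Ca2+, nM (> 0).
#' @param params List with `K_mF` (nM) and `n_F`.
#' @return A list with `omega_ss` (fraction) and `tau_omega` (ms).
#' @examples
#' force_model(160)  # omega_ss = 0.5
#' @export
force_model <- function(Ca, params = list(K_mF = 160, n_F = 3.6)) {
  if (any(Ca <= 0)) stop("`Ca` must be > 0", call. = FALSE)
  r <- (Ca / params$K_mF)^params$n_F
  list(omega_ss = r / (1 + r),
       tau_omega = 4000 * (0.235 + (1 - 0.235) / (1 + r)))
}

# Resolve SS-mode gating algebraically and merge with ODE-mode values.
resolve_gating <- function(gates, ode_values, Vm, Ca) {
  vals <- numeric(length(gates))
  names(vals) <- names(gates)
  for (nm in names(gates)) {
    vals[nm] <- if (gates[[nm]]$mode == "SS") {
      steady_state(gates[[nm]], Vm, Ca)
    } else {
      ode_values[[nm]]
    }
  }
  vals
}

# Per-channel currents (pA/pF) for a full configuration at one state.
config_currents <- function(cfg, gating_values, Vm, Ca) {
  out <- numeric(0)
  for (ch in cfg$channels) {
    if (!ch$enabled) next
    I <- channel_current(ch, gating_values, Vm, Ca)
    if (!is.finite(I)) {
      stop(sprintf("non-finite current in channel '%s' at Vm = %g, Ca = %g",
                   ch$id, Vm, Ca), call. = FALSE)
    }
    out[ch$id] <- I
  }
  out
}

#' Right-hand side of the whole-cell model
#'
#' Implements the membrane-potential balance
#' `dVm/dt = -(sum of channel and exchanger currents + I_app)` (pA/pF, i.e.
#' mV/ms; negative applied current depolarises), the buffered Ca2+ balance
#' `dCa/dt = beta * (influx through Ca2+-carrying channels) - clearance`,
#' first-order force kinetics, and one relaxation ODE per enabled
#' gating variable in `"ODE"` mode. `"SS"`-mode variables are evaluated
#' algebraically at the instantaneous `Vm` (and `Ca`) before currents are
#' computed.
#'
#' @param cfg A [model_config()].
#' @param state A [cell_state()] whose `gating` covers every ODE-mode
#'   variable.
#' @param t Time, ms (unused unless a stimulus closure depends on it).
#' @param Iapp Applied current, pA/pF.
#'
#' @return A list with `derivs` (named: `Vm`, `Ca`, `omega`, one entry per
#'   ODE-mode gating variable) and `currents` (named, pA/pF).
#' @export
cell_rhs <- function(cfg, state, t = 0, Iapp = 0) {
  stopifnot(inherits(cfg, "model_config"), inherits(state, "cell_state"))
  gates <- enabled_gates(cfg)
  active <- purrr::keep(gates, function(g) g$mode == "ODE")
  missing <- setdiff(names(active), names(state$gating))
  if (length(missing)) {
    stop(sprintf("state lacks ODE-mode gating value(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  enabled_exch <- names(cfg$exchangers)[cfg$exchangers]
  if (length(enabled_exch)) {
    stop(sprintf("exchanger(s) %s enabled but no transcribed formulation is bundled; disable them or use a simulatable preset",
                 paste(enabled_exch, collapse = ", ")), call. = FALSE)
  }

  gv <- resolve_gating(gates, state$gating, state$Vm, state$Ca)
  I <- config_currents(cfg, gv, state$Vm, state$Ca)

  dVm <- -(sum(I) + Iapp)

  influx <- 0
  for (ch in cfg$channels) {
    if (ch$enabled && ch$carries_ca) {
      influx <- influx - cfg$flux_conversion * I[[ch$id]]
    }
  }
  dCa <- cfg$beta * influx - cfg$ca_clearance * state$Ca

  fm <- force_model(state$Ca, cfg$force_params)
  domega <- (fm$omega_ss - state$omega) / fm$tau_omega

  dgating <- vapply(names(active), function(nm) {
    g <- active[[nm]]
    (steady_state(g, state$Vm, state$Ca) - state$gating[[nm]]) / tau(g, state$Vm)
  }, numeric(1))

  list(derivs = c(Vm = dVm, Ca = dCa, omega = domega, dgating),
       currents = I)
}

#' Resting state of a configuration
#'
#' Finds the zero-stimulus equilibrium by a nested one-dimensional root
#' solve: for a trial membrane potential all gating variables sit at their
#' steady states and Ca2+ at the equilibrium of its own balance (inner
#' bisection), and the outer solve locates the potential at which the total
#' membrane current vanishes. Degenerate configurations whose residual is
#' identically zero (e.g. all channels disabled) return the initial guess.
#'
#' @param cfg A [model_config()].
#' @param vm_interval Search interval for the resting potential, mV.
#' @param guess Fallback potential for degenerate configurations, mV.
#' @param tol Convergence tolerance passed to the root solvers.
#'
#' @return A [cell_state()] at which the right-hand side norm is ~ 0.
#' @examples
#' resting_state(preset_demo())
#' @export
resting_state <- function(cfg, vm_interval = c(-95, -20), guess = -60,
                          tol = 1e-12) {
  stopifnot(inherits(cfg, "model_config"))
  gates <- enabled_gates(cfg)

  ca_equilibrium <- function(Vm) {
    dca <- function(Ca) {
      gv <- vapply(gates, function(g) steady_state(g, Vm, Ca), numeric(1))
      names(gv) <- names(gates)
      I <- config_currents(cfg, gv, Vm, Ca)
      influx <- 0
      for (ch in cfg$channels) {
        if (ch$enabled && ch$carries_ca) {
          influx <- influx - cfg$flux_conversion * I[[ch$id]]
        }
      }
      cfg$beta * influx - cfg$ca_clearance * Ca
    }
    if (cfg$ca_clearance == 0) return(100)  # Ca2+ not dynamically balanced
    lo <- 1e-3; hi <- 1e6
    if (dca(lo) <= 0) return(lo)
    stats::uniroot(dca, c(lo, hi), tol = tol)$root
  }

  vm_residual <- function(Vm) {
    Ca <- ca_equilibrium(Vm)
    gv <- vapply(gates, function(g) steady_state(g, Vm, Ca), numeric(1))
    names(gv) <- names(gates)
    sum(config_currents(cfg, gv, Vm, Ca))
  }

  probe <- seq(vm_interval[1], vm_interval[2], length.out = 31)
  res <- vapply(probe, vm_residual, numeric(1))
  if (all(abs(res) < 1e-14)) {
    Vm <- guess
  } else {
    sgn <- sign(res)
    idx <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
    if (!length(idx)) {
      stop(sprintf("no membrane-current zero crossing in [%g, %g] mV (residual range [%.3g, %.3g])",
                   vm_interval[1], vm_interval[2], min(res), max(res)),
           call. = FALSE)
    }
    i <- idx[1]
    Vm <- stats::uniroot(vm_residual, c(probe[i], probe[i + 1]),
                         tol = tol)$root
  }

  Ca <- ca_equilibrium(Vm)
  ode_gates <- purrr::keep(gates, function(g) g$mode == "ODE")
  gating <- vapply(ode_gates, function(g) steady_state(g, Vm, Ca), numeric(1))
  names(gating) <- names(ode_gates)
  omega <- force_model(Ca, cfg$force_params)$omega_ss
  cell_state(Vm = Vm, Ca = Ca, gating = gating, omega = omega)
}
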