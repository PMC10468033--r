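#' Whole-cell model configuration
#'
#' Assembles a set of channels, exchanger flags, Ca2+ bookkeeping and
#' gating-variable evaluation modes into a simulatable cell variant. State
#' variables are membrane potential `Vm` (mV), free intracellular `Ca` (nM),
#' the contractile force fraction `omega` and every enabled-channel gating
#' variable in `"ODE"` mode.
#'
#' @param variant Name of the variant.
#' @param channels Named list of [channel()]s (the name must match each
#'   channel's `id`).
#' @param beta Free (unbuffered) fraction of Ca2+ influx, 0 < beta <= 1.
#' @param flux_conversion Factor converting a membrane Ca2+ current in pA/pF
#'   into a concentration flux in nM/ms (cell-geometry dependent; not a
#'   printed model constant).
#' @param ca_clearance Linear Ca2+ clearance rate constant (1/ms), a
#'   PMCA-like extrusion surrogate used by the demo preset.
#' @param exchangers Named logical vector of exchanger/pump enabled flags
#'   (`NCX`, `NaK`, `PMCA`). Enabled exchangers whose formulations are not
#'   bundled make the right-hand side error informatively.
#' @param Cm Membrane capacitance, pF. Currents are already normalized per
#'   pF, so `Cm` is metadata (it enters the flux-conversion estimate only).
#' @param fixed_ions Named list of fixed ion concentrations (mM); `K_o`,
#'   `K_i` are used when a protocol overrides extracellular K+.
#' @param force_params List with `K_mF` (half-activation Ca2+, nM) and `n_F`
#'   (Hill coefficient) of the force submodel.
#' @param modes Named character vector gating-variable name -> `"ODE"`/`"SS"`.
#'   Defaults to each gate's own mode.
#' @param initial_state Optional `cell_state` used by [simulate_cell()].
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant, channels, beta = 0.015,
                         flux_conversion = 26, ca_clearance = 0,
                         exchangers = c(NCX = FALSE, NaK = FALSE, PMCA = FALSE),
                         Cm = 20,
                         fixed_ions = list(K_o = 5.4, K_i = 140,
                                           Na_o = 140, Na_i = 10),
                         force_params = list(K_mF = 160, n_F = 3.6),
                         modes = NULL, initial_state = NULL) {
  stopifnot(is.list(channels), length(channels) > 0)
  names(channels) <- purrr::map_chr(channels, "id")
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]", call. = FALSE)
  if (force_params$K_mF <= 0) stop("`K_mF` must be > 0", call. = FALSE)
  default_modes <- unlist(purrr::map(channels, function(ch) {
    purrr::map_chr(ch$gates, "mode")
  }))
  names(default_modes) <- unlist(purrr::map(channels,
                                            function(ch) names(ch$gates)))
  if (!is.null(modes)) {
    unknown <- setdiff(names(modes), names(default_modes))
    if (length(unknown)) {
      stop(sprintf("unknown gating variable(s) in `modes`: %s (known: %s)",
                   paste(unknown, collapse = ", "),
                   paste(names(default_modes), collapse = ", ")),
           call. = FALSE)
    }
    default_modes[names(modes)] <- toupper(modes)
  }
  if (!all(default_modes %in% c("ODE", "SS"))) {
    stop("gating modes must be 'ODE' or 'SS'", call. = FALSE)
  }
  structure(
    list(variant = variant, channels = channels, beta = beta,
         flux_conversion = flux_conversion, ca_clearance = ca_clearance,
         exchangers = exchangers, Cm = Cm, fixed_ions = fixed_ions,
         force_params = force_params, modes = default_modes,
         initial_state = initial_state),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  en <- purrr::map_lgl(x$channels, "enabled")
  cat(sprintf("<model_config> %s: %d channels enabled (%s), %d gating ODEs, beta = %g\n",
              x$variant, sum(en), paste(names(x$channels)[en], collapse = ", "),
              count_gating_odes(x), x$beta))
  invisible(x)
}

#' Cell state vector
#'
#' @param Vm Membrane potential, mV.
#' @param Ca Free intracellular Ca2+, nM (> 0).
#' @param gating Named numeric vector of ODE-mode gating fractions in \[0, 1\].
#' @param omega Contractile force fraction in \[0, 1\].
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(Vm, Ca, gating = numeric(0), omega = 0) {
  if (Ca <= 0) stop("`Ca` must be > 0", call. = FALSE)
  if (length(gating) && (any(gating < 0) || any(gating > 1))) {
    stop("gating fractions must lie in [0, 1]", call. = FALSE)
  }
  if (omega < 0 || omega > 1) stop("`omega` must lie in [0, 1]", call. = FALSE)
  structure(list(Vm = Vm, Ca = Ca, gating = gating, omega = omega),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> Vm = %.3f mV, Ca = %.2f nM, omega = %.4f, %d gating ODEs\n",
              x$Vm, x$Ca, x$omega, length(x$gating)))
  invisible(x)
}

# Gating variables of enabled channels, in stable order, with resolved modes.
enabled_gates <- function(cfg) {
  out <- list()
  for (ch in cfg$channels) {
    if (!ch$enabled) next
    for (gv in ch$gates) {
      gv$mode <- cfg$modes[[gv$name]]
      gv$channel <- ch$id
      out[[gv$name]] <- gv
    }
  }
  out
}

#' Number of gating ODEs in a configuration
#'
#' Counts enabled-channel gating variables evaluated as full ODEs (the
#' membrane potential, Ca2+ and force equations are excluded). The full
#' model carries 19; the reduced model carries 5.
#'
#' @param cfg A [model_config()].
#' @return Integer count.
#' @examples
#' count_gating_odes(preset_ftm())   # 19
#' count_gating_odes(preset_rtm())   # 5
#' @export
count_gating_odes <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  sum(purrr::map_chr(enabled_gates(cfg), "mode") == "ODE")
}

# ---------------------------------------------------------------------------
# Preset registry
# ---------------------------------------------------------------------------

# Conductance table of the source model (nS/pF): the published values and the
# values of its archived implementation used to reproduce the reference
# stimulated trace (Na+ inactive there). Used by presets and ranking.
source_conductances <- function() {
  tibble::tibble(
    channel   = c("Na", "CaL", "CaT", "K1", "K2", "Ka", "BK", "b", "h",
                  "ANO1", "NSCC"),
    ion_class = c("Na", "Ca", "Ca", "K", "K", "K", "K", "K", "mixed",
                  "Cl", "NS"),
    published = c(NA, 0.6, 0.058, 0.65, 0.04, 0.2, 0.24, 0.004, 0.0542,
                  0.1875, 0.0123),
    cellml    = c(0, 0.6, 0.058, 0.52, 0.032, 0.16, 0.24, 0.004, 0.0542,
                  0.1875, 0.0123)
  )
}

ftm_channel_set <- function(g) {
  list(
    chan_cal(gbar = g[["CaL"]]),
    chan_cat(gbar = g[["CaT"]]),
    chan_na(gbar = g[["Na"]]),
    chan_bk(gbar = g[["BK"]]),
    chan_b(gbar = g[["b"]]),
    chan_declared("K1", g[["K1"]], c("q", "r1", "r2"),
                  c("activation", "inactivation", "inactivation"), ion = "K"),
    chan_declared("K2", g[["K2"]], c("p", "k1", "k2"),
                  c("activation", "inactivation", "inactivation"), ion = "K"),
    chan_declared("Ka", g[["Ka"]], c("s", "x"),
                  c("activation", "inactivation"), ion = "K"),
    chan_declared("h", g[["h"]], "y", "activation", ion = "mixed"),
    chan_declared("ANO1", g[["ANO1"]], "c", "activation", ion = "Cl"),
    chan_declared("NSCC", g[["NSCC"]], character(0), character(0),
                  ion = "NS", carries_ca = TRUE)
  )
}

#' Model presets
#'
#' Ready-made whole-cell variants:
#'
#' * `preset_ftm()` — the full 19-gating-ODE model: all nine channels plus
#'   exchangers. With `conductances = "cellml"` (default) conductances follow
#'   the archived implementation used for the reference stimulated trace
#'   (Na+ conductance 0); `"published"` uses the publication values.
#'   Channels beyond the four with closed-form gating are declared-only
#'   (bookkeeping works; simulation requires a transcribed registry that is
#'   not bundled).
#' * `preset_pilot_rtm()` — conductance-based elimination only (K2, Ka, h and
#'   the Na/K pump removed; `g_K1 = 0.655`, `g_Na = 0.05125`,
#'   `beta = 0.0146`), all remaining gating as ODEs (13).
#' * `preset_rtm()` — the reduced model: elimination plus steady-state
#'   substitution of `x_alpha`, `x_beta`, `b`, `g`, `d`, `f1`, `m`, `h` with
#'   `g_CaL = 0.6`, `g_Na = 0.0895`, `g_K1 = 0.7`, `beta = 0.0169`
#'   (5 gating ODEs: `f2`, `q`, `r1`, `r2`, `c`).
#' * `preset_rtm_long_burst()` — the reduced model with `g_K1 = 0.75` for
#'   long-duration stimulation.
#' * `preset_cal_ss()` — L-type steady-state variants: `"d_only"`
#'   (`g_Na = 0.0703`, `g_K1 = 0.535`, `g_CaL = 0.39`) or `"d_f1"`
#'   (`g_Na = 0.0703`, `g_K1 = 0.60`, `g_CaL = 0.6`).
#' * `preset_demo()` — a fully simulatable variant built from the closed-form
#'   channels only (L-type with `f_Ca = 1`, T-type, Na+ at 0.0895 nS/pF,
#'   BK at a fixed reference Ca2+) plus invented linear leaks (K+ leak
#'   0.05 nS/pF at -84 mV, nonselective leak 0.0123 nS/pF at 0 mV) and a
#'   linear Ca2+ clearance closing the Ca2+ balance. It exists so assembly,
#'   integration and reduction can be exercised end-to-end with zero
#'   transcribed content.
#'
#' @param conductances `"cellml"` or `"published"` column of the conductance
#'   table.
#' @param variant For `preset_cal_ss()`, `"d_only"` or `"d_f1"`.
#' @return A [model_config()].
#' @name presets
NULL

#' @rdname presets
#' @export
preset_ftm <- function(conductances = c("cellml", "published")) {
  conductances <- match.arg(conductances)
  tab <- source_conductances()
  g <- stats::setNames(tab[[conductances]], tab$channel)
  if (is.na(g[["Na"]])) g[["Na"]] <- 0  # published table gives a range only
  model_config("FTM", ftm_channel_set(g), beta = 0.015,
               exchangers = c(NCX = TRUE, NaK = TRUE, PMCA = TRUE))
}

#' @rdname presets
#' @export
preset_pilot_rtm <- function() {
  tab <- source_conductances()
  g <- stats::setNames(tab$cellml, tab$channel)
  g[["K1"]] <- 0.655
  g[["Na"]] <- 0.05125
  chans <- ftm_channel_set(g)
  names(chans) <- purrr::map_chr(chans, "id")
  for (id in c("K2", "Ka", "h")) chans[[id]]$enabled <- FALSE
  model_config("pilot-RTM", chans, beta = 0.0146,
               exchangers = c(NCX = TRUE, NaK = FALSE, PMCA = TRUE))
}

rtm_base <- function(g_K1) {
  tab <- source_conductances()
  g <- stats::setNames(tab$cellml, tab$channel)
  g[["K1"]] <- g_K1
  g[["Na"]] <- 0.0895
  g[["CaL"]] <- 0.6
  chans <- ftm_channel_set(g)
  names(chans) <- purrr::map_chr(chans, "id")
  for (id in c("K2", "Ka", "h")) chans[[id]]$enabled <- FALSE
  model_config("RTM", chans, beta = 0.0169,
               exchangers = c(NCX = TRUE, NaK = FALSE, PMCA = TRUE),
               modes = c(x_alpha = "SS", x_beta = "SS", b = "SS", g = "SS",
                         d = "SS", f1 = "SS", m = "SS", h = "SS"))
}

#' @rdname presets
#' @export
preset_rtm <- function() rtm_base(0.7)

#' @rdname presets
#' @export
preset_rtm_long_burst <- function() {
  cfg <- rtm_base(0.75)
  cfg$variant <- "RTM-long-burst"
  cfg
}

#' @rdname presets
#' @export
preset_cal_ss <- function(variant = c("d_only", "d_f1")) {
  variant <- match.arg(variant)
  tab <- source_conductances()
  g <- stats::setNames(tab$cellml, tab$channel)
  g[["Na"]] <- 0.0703
  if (variant == "d_only") {
    g[["K1"]] <- 0.535; g[["CaL"]] <- 0.39
    modes <- c(d = "SS")
  } else {
    g[["K1"]] <- 0.60; g[["CaL"]] <- 0.6
    modes <- c(d = "SS", f1 = "SS")
  }
  cfg <- model_config(paste0("CaL-SS-", variant), ftm_channel_set(g),
                      beta = 0.015,
                      exchangers = c(NCX = TRUE, NaK = TRUE, PMCA = TRUE),
                      modes = modes)
  cfg
}

#' @rdname presets
#' @export
preset_demo <- function() {
  chans <- list(
    chan_cal(gbar = 0.6),
    chan_cat(gbar = 0.058),
    chan_na(gbar = 0.0895),
    chan_bk(gbar = 0.24),
    chan_leak("Kleak", gbar = 0.05, E = -84, ion = "K"),
    chan_leak("NSleak", gbar = 0.0123, E = 0, ion = "NS")
  )
  model_config("demo", chans, beta = 0.015, flux_conversion = 26,
               ca_clearance = 2e-4,
               exchangers = c(NCX = FALSE, NaK = FALSE, PMCA = FALSE))
}
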