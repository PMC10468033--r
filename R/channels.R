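GAS_CONSTANT <- 8.314462618     # J / (mol K)
FARADAY <- 96485.33212          # C / mol

#' Reversal potentials
#'
#' Either a fixed value in mV or a Nernst potential computed from the
#' transmembrane concentration ratio, `E = (RT / zF) ln(X_out / X_in)`.
#'
#' @param value Fixed reversal potential, mV.
#' @param ion Optional ion label (`"K"`, `"Na"`, `"Ca"`, `"Cl"`, `"NS"`);
#'   used when a protocol overrides extracellular K+.
#' @return An object of class `reversal`.
#' @examples
#' reversal_fixed(-84, ion = "K")
#' @export
reversal_fixed <- function(value, ion = NA_character_) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(mode = "fixed", value = value, ion = ion),
            class = "reversal")
}

#' @rdname reversal_fixed
#' @param X_out,X_in Extra-/intracellular concentrations (same units, > 0).
#' @param valence Ion valence (non-zero integer).
#' @param temperature Temperature in K (default 310).
#' @export
reversal_nernst <- function(X_out, X_in, valence = 1L, temperature = 310,
                            ion = NA_character_) {
  if (valence == 0) stop("`valence` must be non-zero", call. = FALSE)
  structure(list(mode = "nernst", X_out = X_out, X_in = X_in,
                 valence = as.integer(valence), temperature = temperature,
                 ion = ion),
            class = "reversal")
}

#' Evaluate a reversal potential in mV
#'
#' @param rp A `reversal` object.
#' @return Reversal potential, mV.
#' @examples
#' nernst(reversal_nernst(5.4, 140, valence = 1))  # ~ -87 mV at 310 K
#' @export
nernst <- function(rp) {
  stopifnot(inherits(rp, "reversal"))
  if (rp$mode == "fixed") return(rp$value)
  if (rp$X_out <= 0 || rp$X_in <= 0) {
    stop("Nernst concentrations must be > 0", call. = FALSE)
  }
  1000 * GAS_CONSTANT * rp$temperature / (rp$valence * FARADAY) *
    log(rp$X_out / rp$X_in)
}

#' Construct a membrane-current submodel
#'
#' A channel is a maximal conductance (nS/pF), a set of gating variables
#' combined by an open-probability function, and a reversal potential:
#' `I = gbar * open(x; Ca) * (Vm - E)` in pA/pF.
#'
#' @param id Channel identifier.
#' @param gbar Maximal conductance, nS/pF (>= 0).
#' @param gates Named list of [gating_variable()]s (may be empty for
#'   ungated leaks).
#' @param open_prob `function(x, Vm, Ca)` mapping the named vector of gating
#'   values to the open fraction; `NULL` for declared-only channels.
#' @param reversal A `reversal` object.
#' @param source `"closed_form"`, `"synthetic"` (invented plumbing, e.g. demo
#'   leaks) or `"declared"` (present in the source model but with no
#'   transcribed expressions; current evaluation errors).
#' @param carries_ca Does the current contribute Ca2+ flux to Eq. (4)-style
#'   Ca2+ balance?
#' @param needs_ca Does `open_prob` require intracellular Ca2+?
#' @param enabled Include the channel in a model configuration?
#'
#' @return An object of class `channel`.
#' @export
channel <- function(id, gbar, gates = list(), open_prob = NULL,
                    reversal = reversal_fixed(0), source = "closed_form",
                    carries_ca = FALSE, needs_ca = FALSE, enabled = TRUE) {
  if (gbar < 0) stop("`gbar` must be >= 0", call. = FALSE)
  if (length(gates)) names(gates) <- purrr::map_chr(gates, "name")
  structure(
    list(id = id, gbar = gbar, gates = gates, open_prob = open_prob,
         reversal = reversal, source = source,
         carries_ca = isTRUE(carries_ca), needs_ca = isTRUE(needs_ca),
         enabled = isTRUE(enabled)),
    class = "channel"
  )
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel> %s: gbar = %g nS/pF, gates {%s}, E = %s mV [%s]%s\n",
              x$id, x$gbar, paste(names(x$gates), collapse = ", "),
              if (x$reversal$mode == "fixed") format(x$reversal$value) else "Nernst",
              x$source, if (x$enabled) "" else " (disabled)"))
  invisible(x)
}

#' Current through a channel
#'
#' @param ch A [channel()].
#' @param gating_values Named numeric vector of gating fractions in \[0, 1\]
#'   covering every gate of the channel.
#' @param Vm Membrane potential, mV.
#' @param Ca Intracellular Ca2+, nM (required when the channel's open
#'   probability is Ca2+-modulated).
#'
#' @return Current in pA/pF (positive outward).
#' @examples
#' cat <- chan_cat()
#' channel_current(cat, c(b = 0.5, g = 0.5), Vm = 0)
#' @export
channel_current <- function(ch, gating_values, Vm, Ca = NULL) {
  stopifnot(inherits(ch, "channel"))
  if (ch$source == "declared") {
    stop(sprintf("channel '%s' is declared only: its current requires the transcribed parameter registry",
                 ch$id), call. = FALSE)
  }
  if (ch$gbar == 0) return(0)
  need <- names(ch$gates)
  missing <- setdiff(need, names(gating_values))
  if (length(missing)) {
    stop(sprintf("channel '%s': missing gating value(s) %s", ch$id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- gating_values[need]
  if (length(x) && (any(x < 0) || any(x > 1))) {
    stop(sprintf("channel '%s': gating values must lie in [0, 1]", ch$id),
         call. = FALSE)
  }
  if (ch$needs_ca && is.null(Ca)) {
    stop(sprintf("channel '%s' is Ca2+-modulated: supply `Ca`", ch$id),
         call. = FALSE)
  }
  open <- if (is.null(ch$open_prob)) 1 else ch$open_prob(x, Vm, Ca)
  ch$gbar * open * (Vm - nernst(ch$reversal))
}

#' Closed-form channel constructors
#'
#' The four channel submodels whose gating is fully specified in closed form:
#'
#' * `chan_bk()` — large-conductance Ca2+-activated K+ current,
#'   `I = gbar (p_alpha x_alpha + p_beta x_beta)(Vm - E_K)`;
#' * `chan_cat()` — T-type Ca2+ current, `I = gbar b^2 g (Vm - E_Ca)`;
#' * `chan_cal()` — L-type Ca2+ current,
#'   `I = gbar d^2 f_Ca (0.8 f1 + 0.2 f2)(Vm - E_Ca)`;
#' * `chan_na()` — fast voltage-gated Na+ current,
#'   `I = gbar m^3 h (Vm - E_Na)`.
#'
#' Defaults: `E_K = -84` mV (as used for the background K+ equilibrium),
#' `E_Ca = +45` mV and `E_Na = +55` mV as fixed package defaults; the L-type
#' Ca2+-desensitisation factor `f_Ca` defaults to 1 (the closed-form testable
#' surface; the source model's Ca2+-dependent form is not bundled).
#'
#' @param gbar Maximal conductance, nS/pF.
#' @param p_alpha,p_beta BK mixing weights (must sum to 1).
#' @param E Reversal potential, mV.
#' @param f_ca L-type Ca2+ modulation `function(Ca)`; defaults to `function(Ca) 1`.
#' @return A [channel()].
#' @name closed_form_channels
NULL

#' @rdname closed_form_channels
#' @export
chan_bk <- function(gbar = 0.24, p_alpha = 0.65, p_beta = 0.35, E = -84) {
  if (abs(p_alpha + p_beta - 1) > 1e-12) {
    stop("BK mixing weights must sum to 1", call. = FALSE)
  }
  reg <- gating_registry()
  channel(
    "BK", gbar, gates = list(reg$x_alpha, reg$x_beta),
    open_prob = function(x, Vm, Ca) p_alpha * x[["x_alpha"]] + p_beta * x[["x_beta"]],
    reversal = reversal_fixed(E, ion = "K"), needs_ca = FALSE
  )
}

#' @rdname closed_form_channels
#' @export
chan_cat <- function(gbar = 0.058, E = 45) {
  reg <- gating_registry()
  channel(
    "CaT", gbar, gates = list(reg$b, reg$g),
    open_prob = function(x, Vm, Ca) x[["b"]]^2 * x[["g"]],
    reversal = reversal_fixed(E, ion = "Ca"), carries_ca = TRUE
  )
}

#' @rdname closed_form_channels
#' @export
chan_cal <- function(gbar = 0.6, E = 45, f_ca = function(Ca) 1) {
  reg <- gating_registry()
  channel(
    "CaL", gbar, gates = list(reg$d, reg$f1, reg$f2),
    open_prob = function(x, Vm, Ca) {
      x[["d"]]^2 * f_ca(Ca) * (0.8 * x[["f1"]] + 0.2 * x[["f2"]])
    },
    reversal = reversal_fixed(E, ion = "Ca"), carries_ca = TRUE
  )
}

#' @rdname closed_form_channels
#' @export
chan_na <- function(gbar = 0, E = 55) {
  reg <- gating_registry()
  channel(
    "Na", gbar, gates = list(reg$m, reg$h),
    open_prob = function(x, Vm, Ca) x[["m"]]^3 * x[["h"]],
    reversal = reversal_fixed(E, ion = "Na")
  )
}

#' Ungated linear leak (invented plumbing)
#'
#' A simple ohmic leak `I = gbar (Vm - E)` with no gating. Used by the demo
#' preset to close the membrane-potential balance with only closed-form
#' channels; labelled `source = "synthetic"` because it is not part of the
#' source model.
#'
#' @param id Identifier.
#' @param gbar Conductance, nS/pF.
#' @param E Reversal potential, mV.
#' @param ion Ion label.
#' @return A [channel()].
#' @export
chan_leak <- function(id, gbar, E, ion = NA_character_) {
  channel(id, gbar, gates = list(),
          open_prob = NULL,
          reversal = reversal_fixed(E, ion = ion), source = "synthetic")
}

# Background K+ leak of the source model: I_b = gbar (Vm - E_K), no gating.
# Functional form is the standard ohmic leak of the source model (E_K = -84 mV).
chan_b <- function(gbar = 0.004) {
  channel("b", gbar, gates = list(), open_prob = NULL,
          reversal = reversal_fixed(-84, ion = "K"))
}

# Declared-only channels of the source model: gating-variable names and
# conductances are known (summary table / standard notation), but their
# expressions are not transcribed, so currents cannot be evaluated.
chan_declared <- function(id, gbar, gate_names, roles, ion,
                          carries_ca = FALSE) {
  gates <- purrr::map2(gate_names, roles, function(n, r) gating_stub(n, r))
  channel(id, gbar, gates = gates, open_prob = NULL,
          reversal = reversal_fixed(if (identical(ion, "K")) -84 else 0, ion = ion),
          source = "declared", carries_ca = carries_ca)
}
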