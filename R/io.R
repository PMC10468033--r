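#' @importFrom rlang %||% .data
NULL

#' Export gating curves and profiles as CSV
#'
#' `write_curve_csv()` writes a two-column file (`Vm_mV`, `value`) for a
#' steady-state or time-constant curve; `write_iv_csv()` writes an I-V scan
#' with a JSON sidecar recording horizon, holding potential and normalizer;
#' `write_trace_csv()`/`read_trace_csv()` round-trip simulation traces with
#' a JSON metadata sidecar.
#'
#' @param x Object to write.
#' @param path Output file path (sidecars replace the extension with
#'   `.json`).
#' @return The path, invisibly (readers return the object).
#' @name io_csv
NULL

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' @rdname io_csv
#' @param gv A [gating_variable()].
#' @param grid A [voltage_grid()].
#' @param what `"tau"` (ms) or `"ss"` (fraction).
#' @param Ca Fixed Ca2+ for Ca2+-modulated steady states.
#' @export
write_curve_csv <- function(gv, grid, path, what = c("tau", "ss"), Ca = NULL) {
  what <- match.arg(what)
  value <- if (what == "tau") tau(gv, grid$points) else
    steady_state(gv, grid$points, Ca)
  readr::write_csv(tibble::tibble(Vm_mV = grid$points, value = value), path)
  invisible(path)
}

#' @rdname io_csv
#' @export
write_iv_csv <- function(x, path) {
  stopifnot(inherits(x, "iv_curve"))
  readr::write_csv(tibble::as_tibble(x), path)
  meta <- list(channel = attr(x, "channel"),
               horizon_T_ms = attr(x, "horizon_T_ms"),
               holding_Vm = attr(x, "holding_Vm"),
               normalizer_pA_pF = attr(x, "normalizer"),
               modes = as.list(attr(x, "modes")),
               Ca_nM = attr(x, "Ca_nM"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname io_csv
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "sim_trace"))
  readr::write_csv(tibble::as_tibble(x), path)
  jsonlite::write_json(attr(x, "metadata"), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname io_csv
#' @export
read_trace_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else NULL
  if (!is.null(meta$protocol)) {
    meta$protocol <- structure(meta$protocol, class = "stimulus_protocol")
  }
  class(out) <- c("sim_trace", class(out))
  attr(out, "metadata") <- meta
  out
}

# ---------------------------------------------------------------------------
# Declarative YAML configuration files
# ---------------------------------------------------------------------------

config_schema_keys <- c("preset", "variant", "conductances", "beta",
                        "modes", "disable", "enable", "flux_conversion",
                        "ca_clearance")

#' Read and write model configurations as YAML
#'
#' Configurations are serialized declaratively: a `preset` name plus
#' overrides (conductances, `beta`, gating `modes`, channels to `disable`
#' or re-`enable`). Unknown keys are rejected. `write_model_config()`
#' followed by `read_model_config()` reproduces the configuration.
#'
#' @param path YAML file path.
#' @return `read_model_config()`: a [model_config()];
#'   `write_model_config()`: the path, invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  spec <- yaml::read_yaml(path)
  unknown <- setdiff(names(spec), config_schema_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(config_schema_keys, collapse = ", ")), call. = FALSE)
  }
  presets <- list(ftm = preset_ftm, `pilot-rtm` = preset_pilot_rtm,
                  rtm = preset_rtm, `rtm-long-burst` = preset_rtm_long_burst,
                  demo = preset_demo)
  nm <- tolower(spec$preset %||% "demo")
  if (!nm %in% names(presets)) {
    stop(sprintf("unknown preset '%s' (known: %s)", nm,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  cfg <- presets[[nm]]()
  cfg$preset <- nm
  if (!is.null(spec$variant)) cfg$variant <- spec$variant
  plan <- list()
  if (!is.null(spec$disable)) plan$disable <- unlist(spec$disable)
  if (!is.null(spec$modes)) plan$ss <- names(spec$modes)[
    toupper(unlist(spec$modes)) == "SS"]
  ov <- list()
  if (!is.null(spec$conductances)) ov$gbar <- unlist(spec$conductances)
  if (!is.null(spec$beta)) ov$beta <- spec$beta
  if (length(ov)) plan$overrides <- ov
  if (length(plan)) cfg <- apply_reduction(cfg, plan)
  if (!is.null(spec$modes)) {
    ode_back <- names(spec$modes)[toupper(unlist(spec$modes)) == "ODE"]
    if (length(ode_back)) cfg$modes[ode_back] <- "ODE"
  }
  for (id in spec$enable %||% character(0)) {
    if (!id %in% names(cfg$channels)) {
      stop(sprintf("cannot enable unknown channel '%s'", id), call. = FALSE)
    }
    cfg$channels[[id]]$enabled <- TRUE
  }
  if (!is.null(spec$flux_conversion)) cfg$flux_conversion <- spec$flux_conversion
  if (!is.null(spec$ca_clearance)) cfg$ca_clearance <- spec$ca_clearance
  cfg
}

#' @rdname read_model_config
#' @param cfg A [model_config()] (must carry a `preset` name, as configs
#'   read from file do; presets constructed in code can set `cfg$preset`).
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  preset <- cfg$preset %||% tolower(cfg$variant)
  spec <- list(
    preset = preset,
    variant = cfg$variant,
    conductances = as.list(purrr::map_dbl(cfg$channels, "gbar")),
    beta = cfg$beta,
    modes = as.list(cfg$modes),
    disable = names(cfg$channels)[!purrr::map_lgl(cfg$channels, "enabled")],
    flux_conversion = cfg$flux_conversion,
    ca_clearance = cfg$ca_clearance
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Run manifest
#'
#' A reproducibility record emitted alongside tool outputs: command,
#' configuration hash, seed, package version and output paths. Hashes are
#' stable across runs with identical inputs; the timestamp is excluded from
#' any equality comparison.
#'
#' @param command Command or function name.
#' @param cfg Optional [model_config()].
#' @param seed Seed used for any randomized fixture.
#' @param outputs Character vector of output paths.
#' @param path Optional JSON path to write to.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(command, cfg = NULL, seed = NULL,
                         outputs = character(0), path = NULL) {
  man <- list(
    command = command,
    config_hash = if (!is.null(cfg)) config_hash(cfg) else NULL,
    seed = seed,
    tool_version = as.character(utils::packageVersion("hhreduce")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null")
    return(invisible(man))
  }
  man
}

#' Generate the reference fixture set
#'
#' Writes deterministic reference artefacts for the closed-form surface: the
#' time-constant summary table and per-variable tau profiles, I-V curves for
#' the four closed-form channels (all-ODE and all-SS at a 10 ms horizon), a
#' candidate report at a 1 s time scale of interest, a short demo-preset
#' trace, and a run manifest.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (generation is deterministic).
#' @return Character vector of files written, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop(sprintf("directory not writable: %s", dir),
                                     call. = FALSE)
  set.seed(seed)
  files <- character(0)
  grid <- voltage_grid(-100, 200)

  p <- file.path(dir, "tau_table.csv")
  readr::write_csv(tau_table(), p)
  files <- c(files, p)

  reg <- gating_registry()
  for (nm in names(reg)) {
    p <- file.path(dir, sprintf("tau_profile_%s.csv", nm))
    write_curve_csv(reg[[nm]], grid, p, what = "tau")
    files <- c(files, p)
  }

  scan_grid <- voltage_grid(-100, 60)
  chans <- list(BK = chan_bk(), CaT = chan_cat(), CaL = chan_cal(),
                Na = chan_na(gbar = 0.0895))
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    all_ss <- stats::setNames(rep("SS", length(ch$gates)), names(ch$gates))
    curve <- iv_scan(ch, scan_grid, horizon_T = 10, holding_Vm = -55,
                     modes = all_ss, Ca = if (nm == "BK") 200 else NULL)
    p <- file.path(dir, sprintf("iv_%s_T10.csv", nm))
    write_iv_csv(curve, p)
    files <- c(files, p, sidecar_path(p))
  }

  cand <- identify_ss_candidates(preset_demo(), T_interest = 1,
                                 V_span = c(-50, 50))
  p <- file.path(dir, "candidates_T1s.json")
  jsonlite::write_json(tibble::as_tibble(cand), p, digits = NA)
  files <- c(files, p)

  tr <- simulate_cell(preset_demo(), protocol(0, duration = 0, t_max = 1))
  p <- file.path(dir, "demo_trace_1s.csv")
  write_trace_csv(tr, p)
  files <- c(files, p, sidecar_path(p))

  run_manifest("generate_fixtures", cfg = preset_demo(), seed = seed,
               outputs = files, path = file.path(dir, "manifest.json"))
  invisible(c(files, file.path(dir, "manifest.json")))
}
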