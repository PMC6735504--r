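# Run configuration: YAML in, validated config objects out.

.known_sections <- c("controller", "plant", "band_scheme", "relaxometry",
                     "seed", "output", "verbosity")

.apply_section <- function(constructor, overrides, section) {
  allowed <- names(formals(constructor))
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in '%s': %s", section,
                 paste(unknown, collapse = ", ")))
  }
  do.call(constructor, overrides)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with optional sections `controller`, `plant`,
#' `band_scheme`, `relaxometry`, `seed`, `output` and `verbosity`.  Absent
#' keys take the default operating parameters (0.16/0.39 W, 6--7.5 dB goal
#' band, gain 0.0167, 3.2/3.9 SD detection thresholds, 101.6 ms burst
#' interval, 75 s duration, relaxivity 4.44 s^-1 mM^-1); an empty file yields
#' the full default configuration.  Unknown keys and out-of-range values are
#' rejected with field-level messages.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `run_config`: list with `controller` (a
#'   [controller_config()]), `plant` (a [plant_config()]), `band_scheme`,
#'   `relaxometry` (list with `relaxivity_per_s_mM`, `molar_mass_g_mol`,
#'   `radius_mm`, `weighted`), `seed`, `output`, `verbosity`.
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) {
    list()
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  unknown <- setdiff(names(raw), .known_sections)
  if (length(unknown)) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  scheme <- .apply_section(band_scheme,
                           raw$band_scheme %||% list(), "band_scheme")
  plant_over <- raw$plant %||% list()
  plant_over$scheme <- scheme
  relax_defaults <- list(relaxivity_per_s_mM = 4.44,
                         molar_mass_g_mol = 604.71,
                         radius_mm = 1.5, weighted = FALSE)
  relax_over <- raw$relaxometry %||% list()
  unknown_r <- setdiff(names(relax_over), names(relax_defaults))
  if (length(unknown_r)) {
    stop("unknown key(s) in 'relaxometry': ",
         paste(unknown_r, collapse = ", "))
  }
  relax <- utils::modifyList(relax_defaults, relax_over)
  if (relax$relaxivity_per_s_mM <= 0) {
    stop("relaxometry.relaxivity_per_s_mM must be positive")
  }
  cfg <- list(
    controller = .apply_section(controller_config,
                                raw$controller %||% list(), "controller"),
    plant = .apply_section(plant_config, plant_over, "plant"),
    band_scheme = scheme,
    relaxometry = relax,
    seed = as.integer(raw$seed %||% 1L),
    output = raw$output %||% NULL,
    verbosity = raw$verbosity %||% "info"
  )
  structure(cfg, class = "run_config")
}

#' Save a run configuration to YAML
#'
#' Writes the tunable fields of a `run_config` so that
#' [load_run_config()] round-trips to an identical configuration.
#'
#' @param config A `run_config` from [load_run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ctrl <- unclass(config$controller)
  plant <- unclass(config$plant)
  plant$scheme <- NULL
  out <- list(
    controller = ctrl,
    plant = plant,
    relaxometry = config$relaxometry,
    seed = config$seed,
    verbosity = config$verbosity
  )
  if (!is.null(config$output)) out$output <- config$output
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
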