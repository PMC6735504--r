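# Log export and reporting.

#' Export a sonication log to CSV
#'
#' Writes the per-burst long-format table (one row per burst and band:
#' `burst_index`, `target_index`, `time_s`, `detector`, `band`, `power_db`,
#' `applied_power_w`) or the wide per-burst table, both stable schemas for
#' exchange with other tools.
#'
#' @param log A `sonication_log` from [run_sonication()].
#' @param path Output CSV path.
#' @param format `"wide"` (one row per burst) or `"long"` (one row per burst
#'   and band).
#' @return `path`, invisibly.
#' @export
write_sonication_csv <- function(log, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(log, "sonication_log"))
  df <- log$log
  if (format == "long") {
    bands <- c("subharmonic", "harmonic2", "harmonic3", "broadband")
    det <- c(subharmonic = 1L, harmonic2 = 2L, harmonic3 = 2L, broadband = 2L)
    df <- do.call(rbind, lapply(bands, function(b) {
      data.frame(burst_index = df$burst_index,
                 target_index = df$target_index, time_s = df$time_s,
                 detector = det[[b]], band = b,
                 power_db = df[[paste0(b, "_db")]],
                 applied_power_w = df$power_w, stringsAsFactors = FALSE)
    }))
    df <- df[order(df$burst_index, df$band), ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format burst table back into burst spectra
#'
#' @param path CSV written by [write_sonication_csv()] with
#'   `format = "long"`, or any table with columns `burst_index`,
#'   `target_index`, `time_s`, `band`, `power_db`, `applied_power_w`.
#' @param scheme A [band_scheme()].
#' @return A list of [burst_spectrum()] objects ordered by burst index.
#' @export
read_burst_table <- function(path, scheme = band_scheme()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("burst_index", "target_index", "time_s", "band", "power_db")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("burst table is missing column(s): ", paste(missing, collapse = ", "))
  }
  lapply(split(df, df$burst_index), function(g) {
    p <- stats::setNames(g$power_db, g$band)
    burst_spectrum(p, burst_index = g$burst_index[1],
                   target_index = g$target_index[1], time_s = g$time_s[1],
                   applied_power_w = if ("applied_power_w" %in% names(g)) {
                     g$applied_power_w[1]
                   } else {
                     NA_real_
                   },
                   scheme = scheme)
  })
}

#' Write a machine- and human-readable study report
#'
#' Collects whatever result sections are available — a sonication log,
#' an ROI concentration table from [hemispheric_delta()], growth fits and
#' survival results — into a deterministic JSON report plus a plain-text
#' summary.  Sections whose inputs are absent are omitted cleanly.
#'
#' @param path Output path for the JSON report; a `.txt` twin is written
#'   alongside it.
#' @param sonication Optional `sonication_log`.
#' @param roi_table Optional data frame from [hemispheric_delta()].
#' @param growth Optional named list of [fit_doubling_time()] results.
#' @param survival Optional list with elements `km` (named list of
#'   [km_curve()] results) and `logrank` (list of [logrank_test()] results).
#' @return The report list, invisibly.
#' @export
write_report <- function(path, sonication = NULL, roi_table = NULL,
                         growth = NULL, survival = NULL) {
  report <- list()
  if (!is.null(sonication)) {
    stopifnot(inherits(sonication, "sonication_log"))
    s <- sonication$summary
    report$sonication <- list(
      seed = sonication$seed,
      controller_enabled = sonication$controller_enabled,
      n_bursts = s$n_bursts,
      max_power_w = s$max_power_w,
      mean_h_frozen_db = s$mean_h_frozen_db,
      event_fraction = s$event_fraction,
      n_subharmonic_events = s$n_subharmonic_events,
      n_broadband_events = s$n_broadband_events,
      per_target = s$per_target,
      partial = !is.null(sonication$error),
      error = sonication$error
    )
  }
  if (!is.null(roi_table)) report$roi <- roi_table
  if (!is.null(growth)) {
    report$growth <- lapply(growth, function(g) {
      g[c("doubling_days", "v0", "rmse", "finite")]
    })
  }
  if (!is.null(survival)) {
    report$survival <- list()
    if (!is.null(survival$km)) {
      report$survival$km <- lapply(survival$km, function(k) {
        k[c("median", "median_alt")]
      })
    }
    if (!is.null(survival$logrank)) {
      report$survival$logrank <- lapply(survival$logrank, function(l) {
        l[intersect(c("chisq", "df", "p", "method"), names(l))]
      })
    }
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c("soniquant study report", strrep("=", 22))
  if (!is.null(report$sonication)) {
    so <- report$sonication
    lines <- c(lines, "",
               sprintf("Sonication (seed %s, controller %s)%s", so$seed,
                       if (so$controller_enabled) "on" else "off",
                       if (isTRUE(so$partial)) " [PARTIAL]" else ""),
               sprintf("  bursts: %d, max power: %.3f W", so$n_bursts,
                       so$max_power_w),
               sprintf("  mean H after control end: %s dB",
                       format(so$mean_h_frozen_db, digits = 3)),
               sprintf("  events: %d subharmonic, %d broadband (%.2f%% of bursts)",
                       so$n_subharmonic_events, so$n_broadband_events,
                       100 * so$event_fraction),
               "  end-of-control power per target (W):",
               paste0("    ", paste(sprintf("%.3f", so$per_target$end_power_w),
                                    collapse = " ")))
  }
  if (!is.null(report$roi)) {
    lines <- c(lines, "", "Hemispheric R1 comparison:",
               utils::capture.output(print(report$roi, digits = 4)))
  }
  if (!is.null(report$growth)) {
    lines <- c(lines, "", "Tumor doubling times (days):",
               vapply(names(report$growth), function(nm) {
                 sprintf("  %s: %.2f", nm, report$growth[[nm]]$doubling_days)
               }, character(1)))
  }
  if (!is.null(report$survival) && !is.null(report$survival$km)) {
    lines <- c(lines, "", "Median survival (days):",
               vapply(names(report$survival$km), function(nm) {
                 sprintf("  %s: %s", nm,
                         format(report$survival$km[[nm]]$median, digits = 4))
               }, character(1)))
  }
  writeLines(lines, txt)
  invisible(report)
}
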