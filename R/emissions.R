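# Spectral band analysis of passive cavitation detector recordings.
#
# The drive frequency is 230 kHz.  Stable bubble oscillation shows up as
# harmonics (460, 690 kHz); activity near the inertial-cavitation threshold
# shows up as the subharmonic (115 kHz) and as broadband noise, monitored in
# a 40 kHz bin centred on the second hydrophone's 660 kHz resonance.

#' Spectral band scheme for the cavitation detectors
#'
#' Defines the analysis bands used for passive cavitation monitoring at a
#' 230 kHz drive: the subharmonic at half the fundamental, the second and
#' third harmonics, each integrated in narrow 10 kHz bins, and a wide 40 kHz
#' broadband bin centred at 660 kHz (chosen to match the resonance of the
#' broadband hydrophone while excluding both harmonic centers).
#'
#' @param fundamental_hz Drive frequency in Hz.
#' @param narrow_bin_width_hz Width of the subharmonic/harmonic bins.
#' @param broadband_center_hz Center of the broadband bin.
#' @param broadband_bin_width_hz Width of the broadband bin.
#' @return An object of class `band_scheme`: a data frame with one row per
#'   band (`band`, `center_hz`, `width_hz`, `detector`).
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(fundamental_hz = 230e3,
                        narrow_bin_width_hz = 10e3,
                        broadband_center_hz = 660e3,
                        broadband_bin_width_hz = 40e3) {
  stopifnot(fundamental_hz > 0, narrow_bin_width_hz > 0,
            broadband_bin_width_hz > 0)
  bands <- data.frame(
    band = c("subharmonic", "harmonic2", "harmonic3", "broadband"),
    center_hz = c(fundamental_hz / 2, 2 * fundamental_hz, 3 * fundamental_hz,
                  broadband_center_hz),
    width_hz = c(narrow_bin_width_hz, narrow_bin_width_hz,
                 narrow_bin_width_hz, broadband_bin_width_hz),
    # detector 1 is resonant at the subharmonic; detector 2 carries the
    # harmonic and broadband bands
    detector = c(1L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  bb <- bands[bands$band == "broadband", ]
  harm <- bands[bands$band %in% c("harmonic2", "harmonic3"), ]
  lo <- bb$center_hz - bb$width_hz / 2
  hi <- bb$center_hz + bb$width_hz / 2
  if (any(harm$center_hz >= lo & harm$center_hz < hi)) {
    stop("broadband bin must exclude the harmonic centers")
  }
  structure(bands, class = c("band_scheme", "data.frame"))
}

#' Names of the analysis bands
#' @param scheme A [band_scheme()].
#' @return Character vector of band names.
#' @export
band_names <- function(scheme) scheme$band

.band_edges <- function(scheme) {
  data.frame(band = scheme$band,
             lo = scheme$center_hz - scheme$width_hz / 2,
             hi = scheme$center_hz + scheme$width_hz / 2)
}

#' Construct a per-burst band spectrum record
#'
#' A `burst_spectrum` holds one burst's band-resolved emission magnitudes in
#' dB (relative to the configured reference) together with its position in
#' the sonication (burst index, target index, time) and the acoustic power
#' that was applied.
#'
#' @param band_power_db Named numeric vector of band powers in dB; names must
#'   cover the bands of `scheme`.
#' @param burst_index Ordinal burst number (0-based across the sonication).
#' @param target_index Target position in the volumetric pattern (0-based).
#' @param time_s Time since sonication start, seconds.
#' @param applied_power_w Acoustic power applied for this burst, watts.
#' @param scheme A [band_scheme()].
#' @return An object of class `burst_spectrum`.
#' @export
burst_spectrum <- function(band_power_db, burst_index = 0L, target_index = 0L,
                           time_s = 0, applied_power_w = NA_real_,
                           scheme = band_scheme()) {
  missing <- setdiff(band_names(scheme), names(band_power_db))
  if (length(missing)) {
    stop("band_power_db is missing bands: ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(band_power_db))) stop("band powers must be finite")
  if (time_s < 0) stop("time_s must be >= 0")
  structure(
    list(band_power_db = band_power_db[band_names(scheme)],
         burst_index = as.integer(burst_index),
         target_index = as.integer(target_index),
         time_s = time_s,
         applied_power_w = applied_power_w,
         scheme = scheme),
    class = "burst_spectrum"
  )
}

#' @export
print.burst_spectrum <- function(x, ...) {
  cat(sprintf("<burst_spectrum> burst %d, target %d, t = %.3f s, power = %s W\n",
              x$burst_index, x$target_index, x$time_s,
              format(x$applied_power_w, digits = 3)))
  print(round(x$band_power_db, 2))
  invisible(x)
}

#' @export
as.data.frame.burst_spectrum <- function(x, ...) {
  data.frame(burst_index = x$burst_index, target_index = x$target_index,
             time_s = x$time_s, detector = x$scheme$detector,
             band = names(x$band_power_db), power_db = unname(x$band_power_db),
             applied_power_w = x$applied_power_w, stringsAsFactors = FALSE)
}

#' Integrate band powers from a sampled pressure trace
#'
#' Computes the power in each analysis band of a single burst recording.  The
#' full burst is Hann-windowed as one segment (bursts are 5 ms and
#' stationary, so no Welch averaging is used), the periodogram is formed, and
#' power is summed across the periodogram bins falling inside each band
#' (half-open intervals `[center - w/2, center + w/2)`).  Band power is
#' reported as `10*log10` of the summed power; a zero-energy band is guarded
#' to the finite sentinel `silence_floor_db` so downstream arithmetic stays
#' total.
#'
#' @param waveform Numeric vector, the sampled pressure trace of one burst.
#' @param sample_rate Sampling rate in Hz.  Must exceed twice the highest
#'   band edge of `scheme`.
#' @param scheme A [band_scheme()].
#' @param window Window type: `"hann"` (default) or `"rectangular"`.
#' @param silence_floor_db Finite sentinel returned for zero-energy bands.
#' @param ... Metadata passed to [burst_spectrum()] (`burst_index`,
#'   `target_index`, `time_s`, `applied_power_w`).
#' @return A [burst_spectrum()].
#' @examples
#' fs <- 2e6
#' t <- seq(0, 0.005 - 1 / fs, by = 1 / fs)
#' x <- sin(2 * pi * 460e3 * t)
#' compute_band_powers(x, fs)$band_power_db
#' @export
compute_band_powers <- function(waveform, sample_rate, scheme = band_scheme(),
                                window = c("hann", "rectangular"),
                                silence_floor_db = -120, ...) {
  window <- match.arg(window)
  if (length(waveform) == 0) stop("waveform is empty")
  if (!is.numeric(waveform) || any(!is.finite(waveform))) {
    stop("waveform must be finite numeric")
  }
  edges <- .band_edges(scheme)
  nyq_needed <- 2 * max(edges$hi)
  if (sample_rate <= nyq_needed) {
    stop(sprintf(paste0("sample_rate %.3g Hz is below the Nyquist requirement",
                        " for the requested bands (need > %.3g Hz)"),
                 sample_rate, nyq_needed))
  }
  n <- length(waveform)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  } else {
    rep(1, n)
  }
  # one-sided periodogram, normalised so a tone's power is window-invariant
  # up to the usual coherent gain
  xw <- waveform * w
  X <- stats::fft(xw)
  nfreq <- floor(n / 2) + 1
  pgram <- (Mod(X[seq_len(nfreq)])^2) / sum(w^2) / sample_rate
  pgram[-c(1, nfreq)] <- 2 * pgram[-c(1, nfreq)]
  freqs <- (seq_len(nfreq) - 1) * sample_rate / n

  power_db <- vapply(seq_len(nrow(edges)), function(i) {
    sel <- freqs >= edges$lo[i] & freqs < edges$hi[i]
    p <- sum(pgram[sel])
    if (p <= 0) silence_floor_db else max(10 * log10(p), silence_floor_db)
  }, numeric(1))
  names(power_db) <- edges$band
  burst_spectrum(power_db, scheme = scheme, ...)
}

#' Calibrate per-band noise floors
#'
#' Summarises a sequence of burst spectra into per-band noise-floor means and
#' standard deviations (sample SD in dB).  Two floors are used in practice:
#' one measured passively for 3.5 s before each sonication (the reference for
#' harmonic enhancement), and one measured during the low-power bursts of the
#' first 8 s, before microbubbles arrive (the reference for the
#' subharmonic/broadband event thresholds).
#'
#' @param spectra A list of [burst_spectrum()] objects, or a long data frame
#'   with columns `band` and `power_db`.
#' @param source Tag recording where the floor comes from:
#'   `"pre_sonication"` or `"early_burst"`.
#' @return An object of class `noise_floor`: data frame with columns `band`,
#'   `mean_db`, `sd_db`, `n`, plus a `source` attribute.
#' @export
calibrate_noise_floor <- function(spectra,
                                  source = c("pre_sonication", "early_burst")) {
  source <- match.arg(source)
  if (inherits(spectra, "burst_spectrum")) spectra <- list(spectra)
  if (is.data.frame(spectra)) {
    df <- spectra[, c("band", "power_db")]
  } else {
    df <- do.call(rbind, lapply(spectra, function(s) {
      data.frame(band = names(s$band_power_db),
                 power_db = unname(s$band_power_db),
                 stringsAsFactors = FALSE)
    }))
  }
  counts <- table(df$band)
  if (any(counts < 2)) {
    stop("at least 2 spectra per band are required to calibrate a noise floor")
  }
  agg <- do.call(rbind, lapply(split(df$power_db, df$band), function(v) {
    data.frame(mean_db = mean(v), sd_db = stats::sd(v), n = length(v))
  }))
  out <- data.frame(band = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "source") <- source
  class(out) <- c("noise_floor", "data.frame")
  out
}

.floor_stat <- function(floor, band, what = c("mean_db", "sd_db")) {
  what <- match.arg(what)
  i <- match(band, floor$band)
  if (any(is.na(i))) {
    stop("noise floor is missing band(s): ",
         paste(band[is.na(i)], collapse = ", "))
  }
  floor[[what]][i]
}

#' Detect subharmonic and broadband emission events and measure harmonic
#' enhancement
#'
#' Applies the event-detection thresholds to one burst: the subharmonic flag
#' is raised when the subharmonic band power strictly exceeds its early-burst
#' noise-floor mean plus `k_sub` standard deviations, and the broadband flag
#' when the broadband band strictly exceeds mean plus `k_bb` standard
#' deviations.  The harmonic enhancement `H` — the controlled variable — is
#' the arithmetic mean of the second- and third-harmonic band powers (in dB)
#' above their pre-sonication floor means.
#'
#' The event floors come from bursts applied at the starting power during the
#' first seconds of the sonication, before microbubbles arrive; the harmonic
#' reference floor comes from the passive pre-sonication measurement.
#' Boundary equality is treated as a non-event (strict inequality).
#'
#' @param burst A [burst_spectrum()].
#' @param floor_early Early-burst [calibrate_noise_floor()] used for the
#'   subharmonic/broadband thresholds.
#' @param floor_pre Pre-sonication floor used as the harmonic reference;
#'   defaults to `floor_early` when only one floor is available.
#' @param k_sub Threshold multiplier for subharmonic events (default 3.2 SD).
#' @param k_bb Threshold multiplier for broadband events (default 3.9 SD).
#' @return An object of class `detection_result`: list with
#'   `harmonic_enhancement_db`, `subharmonic_flag`, `broadband_flag`.
#' @export
detect_events <- function(burst, floor_early, floor_pre = floor_early,
                          k_sub = 3.2, k_bb = 3.9) {
  stopifnot(inherits(burst, "burst_spectrum"))
  p <- burst$band_power_db
  need <- c("subharmonic", "harmonic2", "harmonic3", "broadband")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("burst is missing band(s): ", paste(missing, collapse = ", "))
  }
  sub_thresh <- .floor_stat(floor_early, "subharmonic", "mean_db") +
    k_sub * .floor_stat(floor_early, "subharmonic", "sd_db")
  bb_thresh <- .floor_stat(floor_early, "broadband", "mean_db") +
    k_bb * .floor_stat(floor_early, "broadband", "sd_db")
  h_ref <- .floor_stat(floor_pre, c("harmonic2", "harmonic3"), "mean_db")
  h <- mean(c(p[["harmonic2"]] - h_ref[1], p[["harmonic3"]] - h_ref[2]))
  structure(
    list(harmonic_enhancement_db = h,
         subharmonic_flag = p[["subharmonic"]] > sub_thresh,
         broadband_flag = p[["broadband"]] > bb_thresh),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> H = %.2f dB, subharmonic: %s, broadband: %s\n",
              x$harmonic_enhancement_db, x$subharmonic_flag, x$broadband_flag))
  invisible(x)
}
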