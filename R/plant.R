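# Synthetic microbubble cavitation plant.
#
# Provides per-burst emission responses to a commanded acoustic power:
# harmonic enhancement grows linearly with the in-situ pressure amplitude
# scaled by the circulating microbubble concentration (bolus arrival followed
# by exponential clearance), while subharmonic and broadband events are drawn
# from a shared latent instability with band-specific pressure thresholds.

#' Configuration of the synthetic cavitation plant
#'
#' All emission magnitudes are in dB on the same (arbitrary) reference scale
#' used by the emissions module; pressures are peak pressure amplitudes in
#' kPa.  The pressure anchor ties acoustic power to pressure via the
#' square-root law calibrated at (0.16 W, 119 kPa).
#'
#' Clearance kinetics are synthetic defaults (single-exponential, half-life
#' 40 s — an order-of-magnitude value for a lipid-shelled agent, not a
#' measured quantity).  The per-target sensitivity multipliers default to a
#' mildly more responsive second location, reproducing in direction the
#' observation that one location consistently needs less power for the same
#' harmonic response.
#'
#' @param arrival_time_s Bolus arrival time at the brain, seconds.
#' @param arrival_ramp_s Duration of the smooth wash-in ramp, seconds.
#' @param clearance_half_life_s Circulatory clearance half-life, seconds.
#'   `Inf` disables clearance.
#' @param harmonic_slope_db_per_kpa Harmonic enhancement per kPa of effective
#'   pressure (pressure x concentration x sensitivity).
#' @param pressure_activation_kpa Effective pressure below which no harmonic
#'   enhancement is produced (activation floor; 0 = pure proportionality).
#' @param anchor_power_w,anchor_pressure_kpa Power/pressure calibration
#'   anchor.
#' @param inertial_threshold_kpa Effective pressure of 50% broadband-event
#'   probability.
#' @param subharmonic_threshold_kpa Effective pressure of 50%
#'   subharmonic-event probability.
#' @param event_sigmoid_width_kpa Logistic width of the event probability.
#' @param event_boost_db Band power added to the subharmonic or broadband
#'   band during an event burst.
#' @param band_noise_sd_db Gaussian noise SD applied to every band power, dB.
#' @param noise_floor_db Baseline band power (the plant's noise floor), dB.
#' @param per_target_sensitivity Positive multiplier per target (length
#'   `n_targets`).
#' @param n_targets Number of targets in the volumetric pattern.
#' @param scheme A [band_scheme()].
#' @return An object of class `plant_config`.
#' @export
plant_config <- function(arrival_time_s = 8,
                         arrival_ramp_s = 1,
                         clearance_half_life_s = 40,
                         harmonic_slope_db_per_kpa = 0.04,
                         pressure_activation_kpa = 0,
                         anchor_power_w = 0.16,
                         anchor_pressure_kpa = 119,
                         inertial_threshold_kpa = 260,
                         subharmonic_threshold_kpa = 250,
                         event_sigmoid_width_kpa = 12,
                         event_boost_db = 25,
                         band_noise_sd_db = 0.5,
                         noise_floor_db = 10,
                         per_target_sensitivity = c(1, 1.12, rep(1, 7)),
                         n_targets = 9,
                         scheme = band_scheme()) {
  stopifnot(arrival_time_s >= 0, arrival_ramp_s >= 0,
            clearance_half_life_s > 0,
            harmonic_slope_db_per_kpa >= 0,
            anchor_power_w > 0, anchor_pressure_kpa > 0,
            inertial_threshold_kpa > 0, subharmonic_threshold_kpa > 0,
            event_sigmoid_width_kpa > 0,
            band_noise_sd_db >= 0,
            length(per_target_sensitivity) == n_targets,
            all(per_target_sensitivity > 0))
  structure(
    list(arrival_time_s = arrival_time_s, arrival_ramp_s = arrival_ramp_s,
         clearance_half_life_s = clearance_half_life_s,
         harmonic_slope_db_per_kpa = harmonic_slope_db_per_kpa,
         pressure_activation_kpa = pressure_activation_kpa,
         anchor_power_w = anchor_power_w,
         anchor_pressure_kpa = anchor_pressure_kpa,
         inertial_threshold_kpa = inertial_threshold_kpa,
         subharmonic_threshold_kpa = subharmonic_threshold_kpa,
         event_sigmoid_width_kpa = event_sigmoid_width_kpa,
         event_boost_db = event_boost_db,
         band_noise_sd_db = band_noise_sd_db,
         noise_floor_db = noise_floor_db,
         per_target_sensitivity = per_target_sensitivity,
         n_targets = as.integer(n_targets),
         scheme = scheme),
    class = "plant_config"
  )
}

#' Deterministic test plants
#'
#' `plant_noise_free()` is a noise-free, event-free, non-clearing plant whose
#' harmonic response is monotone in pressure — the analytically tractable
#' case used to verify controller convergence.  `plant_zero_response()` never
#' produces any harmonic enhancement at any pressure (an adversarial plant
#' that drives the controller upward for the whole control window).
#'
#' @param harmonic_slope_db_per_kpa Harmonic slope; the default makes the
#'   goal band reachable near 0.32 W.
#' @param ... Further arguments to [plant_config()].
#' @return A `plant_config`.
#' @export
plant_noise_free <- function(harmonic_slope_db_per_kpa = 0.04, ...) {
  plant_config(harmonic_slope_db_per_kpa = harmonic_slope_db_per_kpa,
               band_noise_sd_db = 0,
               inertial_threshold_kpa = 1e9,
               subharmonic_threshold_kpa = 1e9,
               clearance_half_life_s = Inf, ...)
}

#' @rdname plant_noise_free
#' @export
plant_zero_response <- function(...) {
  plant_noise_free(harmonic_slope_db_per_kpa = 0, ...)
}

#' Convert acoustic power to peak pressure amplitude
#'
#' Pressure scales as the square root of acoustic power, anchored at a
#' calibrated (power, pressure) pair: `p = p_anchor * sqrt(P / P_anchor)`.
#' With the default anchor (0.16 W, 119 kPa) the 0.16--0.39 W operating
#' range maps to 119--186 kPa.
#'
#' @param power_w Acoustic power in watts (positive).
#' @param anchor_power_w,anchor_pressure_kpa Calibration anchor.
#' @return Peak pressure amplitude in kPa.
#' @examples
#' power_to_pressure(0.39)  # ~186 kPa
#' @export
power_to_pressure <- function(power_w, anchor_power_w = 0.16,
                              anchor_pressure_kpa = 119) {
  if (any(power_w <= 0)) stop("power_w must be positive")
  stopifnot(anchor_power_w > 0, anchor_pressure_kpa > 0)
  anchor_pressure_kpa * sqrt(power_w / anchor_power_w)
}

#' Relative microbubble concentration after bolus injection
#'
#' Zero before arrival, a smooth half-cosine ramp to the peak (normalised to
#' 1) over the wash-in time, then single-exponential clearance with the
#' configured half-life.
#'
#' @param t Time since sonication start, seconds (vectorised).
#' @param config A [plant_config()].
#' @return Relative concentration in `[0, 1]`.
#' @export
bubble_concentration <- function(t, config) {
  stopifnot(all(t >= 0))
  t0 <- config$arrival_time_s
  ramp <- config$arrival_ramp_s
  hl <- config$clearance_half_life_s
  conc <- numeric(length(t))
  rising <- t >= t0 & t < t0 + ramp
  if (ramp > 0) {
    conc[rising] <- 0.5 * (1 - cos(pi * (t[rising] - t0) / ramp))
  }
  decaying <- t >= t0 + ramp
  conc[decaying] <- if (is.finite(hl)) {
    0.5^((t[decaying] - t0 - ramp) / hl)
  } else {
    1
  }
  conc
}

.event_probability <- function(p_eff, threshold, width) {
  stats::plogis((p_eff - threshold) / width)
}

#' Simulate one burst response of the cavitation plant
#'
#' Returns the band-resolved emission spectrum produced by one burst at the
#' commanded power.  Harmonic band powers are the noise floor plus
#' `slope * (pressure * concentration * sensitivity - activation)+` plus
#' Gaussian band noise.  Subharmonic and broadband events are Bernoulli draws
#' whose probabilities are logistic in the same effective pressure, with
#' band-specific thresholds but a single shared latent instability draw per
#' burst (both event types concentrate at the same sensitive locations); an
#' event adds `event_boost_db` to the corresponding band.
#'
#' @param target_index 0-based target index.
#' @param power_w Commanded acoustic power in watts (0 allowed: passive
#'   listening).
#' @param time_s Time since sonication start, seconds.
#' @param config A [plant_config()].
#' @param stream A random stream from [rng_streams()] (one per target); when
#'   `NULL` the global RNG is used.
#' @param burst_index Ordinal burst number recorded in the output.
#' @return A [burst_spectrum()].
#' @export
plant_respond <- function(target_index, power_w, time_s, config,
                          stream = NULL, burst_index = 0L) {
  stopifnot(inherits(config, "plant_config"),
            target_index >= 0, target_index < config$n_targets,
            power_w >= 0, time_s >= 0)
  pressure <- if (power_w > 0) {
    power_to_pressure(power_w, config$anchor_power_w,
                      config$anchor_pressure_kpa)
  } else {
    0
  }
  conc <- bubble_concentration(time_s, config)
  sens <- config$per_target_sensitivity[target_index + 1L]
  p_eff <- pressure * conc * sens

  enh <- config$harmonic_slope_db_per_kpa *
    max(p_eff - config$pressure_activation_kpa, 0)

  draw <- function() {
    list(noise = stats::rnorm(4, sd = config$band_noise_sd_db),
         u = stats::runif(1))
  }
  d <- if (is.null(stream)) draw() else stream_eval(stream, draw)

  p_sub <- .event_probability(p_eff, config$subharmonic_threshold_kpa,
                              config$event_sigmoid_width_kpa)
  p_bb <- .event_probability(p_eff, config$inertial_threshold_kpa,
                             config$event_sigmoid_width_kpa)
  sub_event <- d$u < p_sub
  bb_event <- d$u < p_bb

  floor <- config$noise_floor_db
  powers <- c(
    subharmonic = floor + d$noise[1] + if (sub_event) config$event_boost_db else 0,
    harmonic2 = floor + enh + d$noise[2],
    harmonic3 = floor + enh + d$noise[3],
    broadband = floor + d$noise[4] + if (bb_event) config$event_boost_db else 0
  )
  burst_spectrum(powers, burst_index = burst_index,
                 target_index = target_index, time_s = time_s,
                 applied_power_w = if (power_w > 0) power_w else NA_real_,
                 scheme = config$scheme)
}

#' Synthesize a waveform realizing requested band powers
#'
#' Builds a sampled pressure trace whose band-integrated powers (as computed
#' by [compute_band_powers()] with the same window) match the requested band
#' powers: one tone per band at the band center, with amplitude calibrated
#' numerically against a unit tone, plus optional white noise.  Lets the
#' band-level plant be exercised end-to-end through the waveform-level
#' emissions pipeline; the round trip recovers the inputs within 0.5 dB.
#'
#' @param band_power_db Named band powers in dB (names from the scheme), or a
#'   [burst_spectrum()].
#' @param sample_rate Sampling rate in Hz.
#' @param duration_s Trace duration in seconds; must cover at least two
#'   periods of the lowest band center.
#' @param scheme A [band_scheme()].
#' @param white_noise_db Per-sample white-noise power in dB, or `NULL` for a
#'   noiseless trace.
#' @param window Window assumed by the downstream band integrator.
#' @return Numeric vector: the sampled trace.
#' @export
synthesize_waveform <- function(band_power_db, sample_rate, duration_s = 0.005,
                                scheme = band_scheme(), white_noise_db = NULL,
                                window = "hann") {
  if (inherits(band_power_db, "burst_spectrum")) {
    band_power_db <- band_power_db$band_power_db
  }
  if (any(!is.finite(band_power_db))) stop("band powers must be finite")
  lowest <- min(scheme$center_hz)
  if (duration_s < 2 / lowest) {
    stop("duration_s must cover at least two periods of the lowest band")
  }
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  for (b in names(band_power_db)) {
    i <- match(b, scheme$band)
    if (is.na(i)) stop("unknown band: ", b)
    f <- scheme$center_hz[i]
    unit <- sin(2 * pi * f * t)
    ref_db <- compute_band_powers(unit, sample_rate, scheme,
                                  window = window)$band_power_db[[b]]
    amp <- 10^((band_power_db[[b]] - ref_db) / 20)
    x <- x + amp * unit
  }
  if (!is.null(white_noise_db)) {
    x <- x + stats::rnorm(n, sd = 10^(white_noise_db / 20))
  }
  x
}
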