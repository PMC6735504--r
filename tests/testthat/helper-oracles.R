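# Independent oracles used across the suite.

# Band power by explicit DFT summation (no stats::fft), same Hann window and
# one-sided periodogram normalisation as the band integrator, but computed by
# direct matrix evaluation of the Fourier sums over the band's bins only.
oracle_band_power_db <- function(waveform, sample_rate, lo_hz, hi_hz,
                                 silence_floor_db = -120) {
  n <- length(waveform)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  xw <- waveform * w
  freqs <- (seq_len(floor(n / 2) + 1) - 1) * sample_rate / n
  bins <- which(freqs >= lo_hz & freqs < hi_hz)
  if (!length(bins)) return(silence_floor_db)
  total <- 0
  tt <- seq_len(n) - 1
  for (b in bins) {
    k <- b - 1
    re <- sum(xw * cos(2 * pi * k * tt / n))
    im <- -sum(xw * sin(2 * pi * k * tt / n))
    p <- (re^2 + im^2) / sum(w^2) / sample_rate
    if (k != 0 && b != floor(n / 2) + 1) p <- 2 * p
    total <- total + p
  }
  if (total <= 0) silence_floor_db else max(10 * log10(total), silence_floor_db)
}

# Kaplan-Meier product-limit by hand: S(t) over unique event times.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Closed-loop steady power by direct iteration of the control law on a
# noise-free linear plant H(p_kpa) = slope * p_kpa (per-target cycle time
# n_targets * burst_interval).  Independent of run_sonication's bookkeeping.
oracle_steady_power <- function(slope, config = controller_config(),
                                anchor_power = 0.16, anchor_pressure = 119) {
  power <- config$p_start_w
  h_set <- config$h_setpoint_db
  cycle <- config$n_targets * config$burst_interval_s
  t <- ceiling(config$bubble_delay_s / cycle) * cycle
  while (t < config$control_end_s) {
    h <- slope * anchor_pressure * sqrt(power / anchor_power)
    if (h < config$goal_band_db[1] || h > config$goal_band_db[2]) {
      f <- max(1 + config$p_gain * (h_set - h), 0.05)
      power <- min(power * f^2, config$p_max_w)
    }
    t <- t + cycle
  }
  power
}
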