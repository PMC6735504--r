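test_that("power-to-pressure follows the square-root anchor law", {
  expect_equal(power_to_pressure(0.16), 119)            # anchor identity
  expect_equal(round(power_to_pressure(0.39)), 186)     # top of the range
  expect_equal(power_to_pressure(0.64), 238)            # 4x power = 2x pressure
  expect_error(power_to_pressure(0), "positive")
  expect_error(power_to_pressure(-1), "positive")
})

test_that("bubble concentration ramps to a normalised peak then decays", {
  cfg <- plant_config(arrival_time_s = 8, arrival_ramp_s = 1,
                      clearance_half_life_s = 40)
  expect_equal(bubble_concentration(0, cfg), 0)
  expect_equal(bubble_concentration(7.9, cfg), 0)
  expect_equal(bubble_concentration(9, cfg), 1)          # arrival + ramp
  expect_equal(bubble_concentration(49, cfg), 0.5)       # one half-life later
  # monotone non-increasing after the peak
  tt <- seq(9, 75, by = 0.5)
  expect_true(all(diff(bubble_concentration(tt, cfg)) <= 0))
})

test_that("pre-arrival bursts show no harmonic enhancement at any power", {
  cfg <- plant_config(band_noise_sd_db = 0)
  for (p in c(0.16, 0.39, 5)) {
    sp <- plant_respond(0, p, time_s = 2, cfg)
    expect_equal(unname(sp$band_power_db[c("harmonic2", "harmonic3")]),
                 rep(cfg$noise_floor_db, 2))
  }
})

test_that("harmonic response is linear in effective pressure", {
  cfg <- plant_config(arrival_time_s = 0, arrival_ramp_s = 0,
                      clearance_half_life_s = Inf, band_noise_sd_db = 0,
                      per_target_sensitivity = rep(1, 9))
  sp <- plant_respond(0, 0.16, time_s = 10, cfg)
  h <- sp$band_power_db[["harmonic2"]] - cfg$noise_floor_db
  expect_equal(h, cfg$harmonic_slope_db_per_kpa * 119)
  # 4x power doubles pressure, doubles the enhancement
  sp4 <- plant_respond(0, 0.64, time_s = 10, cfg)
  expect_equal(sp4$band_power_db[["harmonic2"]] - cfg$noise_floor_db, 2 * h)
})

test_that("event probability is a sigmoid tail far below threshold and 1/2 at it", {
  # far below threshold: probability is negligible -> no events in 1e4 bursts
  cfg_low <- plant_config(arrival_time_s = 0, arrival_ramp_s = 0,
                          clearance_half_life_s = Inf,
                          inertial_threshold_kpa = 400,
                          subharmonic_threshold_kpa = 400,
                          event_sigmoid_width_kpa = 12,
                          per_target_sensitivity = rep(1, 9))
  expect_lt(plogis((119 - 400) / 12), 1e-6)

  # at the threshold pressure the event rate is Bernoulli(1/2)
  p_at <- 0.16  # -> 119 kPa
  cfg_at <- plant_config(arrival_time_s = 0, arrival_ramp_s = 0,
                         clearance_half_life_s = Inf,
                         inertial_threshold_kpa = 119,
                         subharmonic_threshold_kpa = 119,
                         event_sigmoid_width_kpa = 12,
                         per_target_sensitivity = rep(1, 9))
  st <- rng_streams(11, 1)
  n <- 1e4
  hits <- vapply(seq_len(n), function(i) {
    sp <- plant_respond(0, p_at, time_s = 10, cfg_at, stream = st[[1]])
    sp$band_power_db[["broadband"]] > cfg_at$noise_floor_db + 10
  }, logical(1))
  expect_equal(mean(hits), 0.5, tolerance = 0.04)  # 0.5 +/- 0.02 claimed
})

test_that("event counts over long runs fall within binomial confidence bounds", {
  # a pressure giving a known intermediate rate
  width <- 12
  thr <- 130
  p_true <- plogis((119 - thr) / width)
  cfg <- plant_config(arrival_time_s = 0, arrival_ramp_s = 0,
                      clearance_half_life_s = Inf,
                      inertial_threshold_kpa = thr,
                      subharmonic_threshold_kpa = thr,
                      event_sigmoid_width_kpa = width,
                      per_target_sensitivity = rep(1, 9))
  st <- rng_streams(5, 1)
  n <- 5000
  hits <- vapply(seq_len(n), function(i) {
    sp <- plant_respond(0, 0.16, time_s = 10, cfg, stream = st[[1]])
    sp$band_power_db[["broadband"]] > cfg$noise_floor_db + 10
  }, logical(1))
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(hits) - p_true), 4 * se)
})

test_that("waveform synthesis round-trips band powers within 0.5 dB", {
  fs <- 2e6
  req <- c(subharmonic = 10, harmonic2 = 16, harmonic3 = 13, broadband = 10)
  x <- synthesize_waveform(req, fs)
  got <- compute_band_powers(x, fs)$band_power_db
  expect_true(all(abs(got - req) < 0.5))

  # all-floor request round-trips too
  flat <- rep(10, 4)
  names(flat) <- names(req)
  got2 <- compute_band_powers(synthesize_waveform(flat, fs), fs)$band_power_db
  expect_true(all(abs(got2 - flat) < 0.5))
})

test_that("a synthesised broadband event trips the 3.9 SD detector", {
  fs <- 2e6
  floor_db <- 10
  fl <- structure(data.frame(band = c("subharmonic", "harmonic2",
                                      "harmonic3", "broadband"),
                             mean_db = floor_db, sd_db = 1, n = 20L),
                  class = c("noise_floor", "data.frame"))
  req <- c(subharmonic = floor_db, harmonic2 = floor_db,
           harmonic3 = floor_db, broadband = floor_db + 25)
  sp <- compute_band_powers(synthesize_waveform(req, fs), fs)
  det <- detect_events(sp, fl)
  expect_true(det$broadband_flag)
  expect_false(det$subharmonic_flag)
})

test_that("waveform synthesis rejects too-short durations", {
  expect_error(synthesize_waveform(c(harmonic2 = 10), 2e6, duration_s = 1e-5),
               "two periods")
})

test_that("lower target sensitivity forces a higher steady-state power", {
  lo <- plant_noise_free()
  lo$per_target_sensitivity <- rep(0.85, 9)
  hi <- plant_noise_free()
  hi$per_target_sensitivity <- rep(1.1, 9)
  p_lo <- run_sonication(lo, seed = 1)$summary$per_target$end_power_w
  p_hi <- run_sonication(hi, seed = 1)$summary$per_target$end_power_w
  expect_true(all(p_lo > p_hi))
})

test_that("the analytic fixed point reproduces the setpoint enhancement", {
  cfg <- plant_noise_free(arrival_ramp_s = 0)
  h_set <- 6.75
  p_star_kpa <- cfg$pressure_activation_kpa +
    h_set / cfg$harmonic_slope_db_per_kpa
  power_star <- cfg$anchor_power_w * (p_star_kpa / cfg$anchor_pressure_kpa)^2
  sp <- plant_respond(0, power_star, time_s = 10, cfg)
  expect_equal(sp$band_power_db[["harmonic2"]] - cfg$noise_floor_db, h_set,
               tolerance = 1e-10)
})
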