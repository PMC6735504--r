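mk_det <- function(h, sub = FALSE, bb = FALSE) {
  structure(list(harmonic_enhancement_db = h, subharmonic_flag = sub,
                 broadband_flag = bb), class = "detection_result")
}

mk_controlling <- function(power = 0.16, config = controller_config()) {
  st <- target_state(0, config)
  st$phase <- "controlling"
  st$power_w <- power
  st
}

test_that("power is held and recorded when H is inside the goal band", {
  cfg <- controller_config()
  st <- mk_controlling(0.2)
  st2 <- proportional_update(st, mk_det(6.75), cfg)
  expect_equal(st2$power_w, 0.2)
  expect_equal(st2$goal_hit_powers, 0.2)
  # band edges are inside
  expect_equal(proportional_update(st, mk_det(6.0), cfg)$power_w, 0.2)
  expect_equal(proportional_update(st, mk_det(7.5), cfg)$power_w, 0.2)
})

test_that("a low H drives the power up, within the cap", {
  cfg <- controller_config()
  st <- mk_controlling(0.16)
  st2 <- proportional_update(st, mk_det(0), cfg)
  expect_gt(st2$power_w, 0.16)
  expect_lte(st2$power_w, 0.39)
  # the pressure-domain law: power * (1 + gain * error)^2
  expect_equal(st2$power_w, 0.16 * (1 + 0.0167 * 6.75)^2)
})

test_that("persistent zero response saturates at the power cap", {
  cfg <- controller_config()
  st <- mk_controlling(0.16)
  powers <- numeric(50)
  for (i in 1:50) {
    st <- proportional_update(st, mk_det(0), cfg)
    powers[i] <- st$power_w
  }
  expect_true(all(diff(powers) >= 0))       # monotone climb
  expect_equal(powers[50], 0.39)            # clamped, never above
  expect_true(all(powers <= 0.39))
})

test_that("a high H drives power down and cannot cross zero", {
  cfg <- controller_config()
  st <- mk_controlling(0.3)
  st2 <- proportional_update(st, mk_det(12), cfg)
  expect_lt(st2$power_w, 0.3)
  expect_gt(st2$power_w, 0)
  # absurdly high H still leaves a positive power (guarded factor)
  st3 <- proportional_update(st, mk_det(1e4), cfg)
  expect_gt(st3$power_w, 0)
})

test_that("non-finite H skips the burst and holds power", {
  cfg <- controller_config()
  st <- mk_controlling(0.2)
  expect_warning(st2 <- proportional_update(st, mk_det(NaN), cfg),
                 "non-finite")
  expect_equal(st2$power_w, 0.2)
})

test_that("safety reduction is 25%, terminal, and applied exactly once", {
  cfg <- controller_config()
  st <- mk_controlling(0.32)
  st2 <- safety_reduce(st, cfg)
  expect_equal(st2$power_w, 0.24)
  expect_equal(st2$phase, "frozen")
  expect_true(st2$reduced_flag)
  # second event on the reduced target is a no-op
  st3 <- safety_reduce(st2, cfg)
  expect_equal(st3$power_w, 0.24)

  st4 <- safety_reduce(mk_controlling(0.16), cfg)
  expect_equal(st4$power_w, 0.12)
})

test_that("end-of-control freeze sets the mean goal-hit power or holds", {
  cfg <- controller_config()
  st <- mk_controlling(0.28)
  st$goal_hit_powers <- c(0.30, 0.34)
  expect_equal(end_of_control_freeze(st, cfg)$power_w, 0.32)

  st_one <- mk_controlling(0.2)
  st_one$goal_hit_powers <- 0.38
  expect_equal(end_of_control_freeze(st_one, cfg)$power_w, 0.38)

  st_none <- mk_controlling(0.22)
  frozen <- end_of_control_freeze(st_none, cfg)
  expect_equal(frozen$power_w, 0.22)     # fallback: hold current power
  expect_equal(frozen$phase, "frozen")
})

test_that("closed loop on a noise-free plant reaches and holds the goal band", {
  log <- run_sonication(plant_noise_free(), seed = 1)
  cfg <- log$config
  frozen <- log$log[log$log$time_s >= cfg$control_end_s, ]
  mean_h <- mean(frozen$h_db)
  expect_gte(mean_h, cfg$goal_band_db[1])
  expect_lte(mean_h, cfg$goal_band_db[2])
  # H enters the goal band within the control window for every target
  ctl <- log$log[log$log$time_s >= cfg$bubble_delay_s &
                   log$log$time_s < cfg$control_end_s, ]
  hit <- tapply(ctl$h_db, ctl$target_index, function(h) {
    any(h >= cfg$goal_band_db[1] & h <= cfg$goal_band_db[2])
  })
  expect_true(all(hit))
})

test_that("steady power matches the independent iteration oracle within 2%", {
  plant <- plant_noise_free(arrival_ramp_s = 0)
  plant$per_target_sensitivity <- rep(1, 9)
  log <- run_sonication(plant, seed = 1)
  expected <- oracle_steady_power(plant$harmonic_slope_db_per_kpa)
  got <- log$summary$per_target$end_power_w
  expect_true(all(abs(got - expected) / expected < 0.02))
})

test_that("the power clamp and phase gates hold on every log", {
  for (plant in list(plant_noise_free(), plant_zero_response(),
                     plant_config())) {
    log <- run_sonication(plant, seed = 3)$log
    cfg <- controller_config()
    expect_true(all(log$power_w > 0 & log$power_w <= cfg$p_max_w))
    # no modulation before the bolus-arrival gate
    pre <- log[log$time_s < cfg$bubble_delay_s, ]
    expect_true(all(pre$power_w == cfg$p_start_w))
    # no increase after the control window, per target
    post <- log[log$time_s >= cfg$control_end_s, ]
    for (tgt in unique(post$target_index)) {
      expect_true(all(diff(post$power_w[post$target_index == tgt]) <= 0))
    }
  }
})

test_that("the zero-response adversary is clamped at the cap", {
  log <- run_sonication(plant_zero_response(), seed = 1)
  expect_equal(log$summary$max_power_w, 0.39)
  expect_true(all(log$log$power_w <= 0.39))
})

test_that("identical seeds give bit-identical logs, different seeds differ", {
  a <- run_sonication(plant_config(), seed = 9)
  b <- run_sonication(plant_config(), seed = 9)
  expect_identical(a$log, b$log)
  c <- run_sonication(plant_config(), seed = 10)
  expect_false(identical(a$log, c$log))
})

test_that("targets are controlled independently", {
  base <- plant_noise_free()
  pert <- plant_noise_free()
  pert$per_target_sensitivity[4] <- 0.7  # perturb target index 3 only
  la <- run_sonication(base, seed = 2)$log
  lb <- run_sonication(pert, seed = 2)$log
  others <- la$target_index != 3
  expect_identical(la$power_w[others], lb$power_w[others])
  expect_false(identical(la$power_w[!others], lb$power_w[!others]))
})

test_that("a detection event yields one 25% reduction then a terminal freeze", {
  # plant with a low inertial threshold: events certain once bubbles arrive
  plant <- plant_config(band_noise_sd_db = 0, inertial_threshold_kpa = 50,
                        subharmonic_threshold_kpa = 1e9,
                        event_sigmoid_width_kpa = 1)
  log <- run_sonication(plant, seed = 4)
  df <- log$log
  cfg <- log$config
  for (tgt in 0:8) {
    tr <- df[df$target_index == tgt & df$time_s >= cfg$bubble_delay_s, ]
    first_flag <- which(tr$broadband_flag)[1]
    expect_false(is.na(first_flag))
    p_at_flag <- tr$power_w[first_flag]
    after <- tr$power_w[-seq_len(first_flag)]
    # exactly one reduction to 75%, then constant
    expect_equal(unique(after), 0.75 * p_at_flag)
  }
  expect_true(all(log$summary$per_target$reduced))
  expect_true(all(log$summary$per_target$phase == "frozen"))
})

test_that("with the controller disabled the power is fixed throughout", {
  log <- run_sonication(plant_config(), controller_enabled = FALSE,
                        fixed_power_w = 0.3, seed = 5)
  expect_true(all(log$log$power_w == 0.3))
  expect_true(all(!log$summary$per_target$reduced))
})

test_that("uncontrolled high power on a sensitive plant floods the log with events", {
  plant <- plant_config(inertial_threshold_kpa = 150,
                        event_sigmoid_width_kpa = 10)
  log <- run_sonication(plant, controller_enabled = FALSE,
                        fixed_power_w = 0.39, seed = 6)
  post <- log$log[log$log$time_s >= 8 & log$log$time_s <= 40, ]
  expect_gt(mean(post$broadband_flag), 0.25)  # sustained fraction of bursts
})

test_that("a plant failure mid-run returns a partial log with an error marker", {
  dies_at <- 200
  plant_fn <- function(target, power, time, burst) {
    if (burst >= dies_at) stop("detector dropout")
    sp <- plant_respond(target, power, time, plant_noise_free(),
                        burst_index = burst)
    sp
  }
  log <- run_sonication(plant_fn, seed = 1)
  expect_match(log$error, "detector dropout")
  expect_equal(nrow(log$log), dies_at)
})

test_that("global freeze mode reduces every target on one event", {
  plant <- plant_config(band_noise_sd_db = 0, inertial_threshold_kpa = 50,
                        subharmonic_threshold_kpa = 1e9,
                        event_sigmoid_width_kpa = 1)
  cfg <- controller_config(global_freeze = TRUE)
  log <- run_sonication(plant, cfg, seed = 4)
  expect_true(all(log$summary$per_target$reduced))
  # all targets freeze at the first event, i.e. within one cycle of it
  df <- log$log
  first_ev <- min(df$time_s[df$broadband_flag])
  later <- df[df$time_s > first_ev + 9 * cfg$burst_interval_s, ]
  for (tgt in 0:8) {
    expect_equal(length(unique(later$power_w[later$target_index == tgt])), 1)
  }
})
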