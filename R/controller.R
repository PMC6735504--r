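# Closed-loop per-target acoustic power controller.
#
# Each target in the volumetric sonication is controlled independently.  The
# controlled variable is the harmonic enhancement H (mean dB elevation of the
# 2nd and 3rd harmonic bands above the pre-sonication noise floor).  Power is
# held at the starting level until the microbubble bolus arrives, then a
# proportional controller in the pressure domain steers H into the goal band;
# at the end of the control window the power is frozen at the mean of all
# powers that achieved the goal.  Detection of subharmonic or broadband
# emission triggers a single 25% power reduction followed by a terminal
# freeze.

#' Controller configuration
#'
#' Defaults are the operating parameters of the feedback-controlled
#' volumetric sonication: start at 0.16 W, cap at 0.39 W, 6--7.5 dB harmonic
#' goal band, proportional gain 0.0167 per dB in the pressure domain, a 3.5 s
#' passive baseline, control starting 8 s after sonication start (bolus
#' transit time) and ending at 25 s, 75 s total exposure of 5 ms bursts
#' interleaved over 9 targets at 101.6 ms intervals (per-target PRF 1.1 Hz).
#'
#' @param p_start_w Starting acoustic power, W.
#' @param p_max_w Maximum allowed acoustic power, W.
#' @param goal_band_db Two-element numeric, the harmonic-enhancement goal
#'   band in dB above the noise floor.  The upper edge is configurable (7.5
#'   by default; 7.7 is a defensible alternative).
#' @param p_gain Proportional gain applied to the dB error in the pressure
#'   domain, per dB.
#' @param h_setpoint_db Setpoint used in the proportional update; defaults to
#'   the goal-band midpoint.
#' @param baseline_duration_s Passive noise-floor acquisition before the
#'   sonication, s.
#' @param bubble_delay_s Time allowed for the microbubbles to reach the
#'   brain; no modulation before this, s.
#' @param control_end_s Time after which power is never increased, s.
#' @param total_duration_s Total sonication duration, s (75 with
#'   microbubbles, 30 for a baseline sonication without).
#' @param reduction_fraction Fractional power reduction on a detection event.
#' @param burst_length_s Burst duration, s.
#' @param burst_interval_s Interval between consecutive bursts (across
#'   targets), s.
#' @param n_targets Number of interleaved targets.
#' @param k_sub,k_bb Detection thresholds in noise-floor SDs for the
#'   subharmonic and broadband bands.
#' @param global_freeze If `TRUE`, a detection event on any target reduces
#'   and freezes every target (the paper's phrasing read globally); default
#'   is per-target.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(p_start_w = 0.16,
                              p_max_w = 0.39,
                              goal_band_db = c(6.0, 7.5),
                              p_gain = 0.0167,
                              h_setpoint_db = NULL,
                              baseline_duration_s = 3.5,
                              bubble_delay_s = 8,
                              control_end_s = 25,
                              total_duration_s = 75,
                              reduction_fraction = 0.25,
                              burst_length_s = 0.005,
                              burst_interval_s = 0.1016,
                              n_targets = 9,
                              k_sub = 3.2,
                              k_bb = 3.9,
                              global_freeze = FALSE) {
  stopifnot(p_start_w > 0, p_start_w <= p_max_w,
            length(goal_band_db) == 2, goal_band_db[1] < goal_band_db[2],
            p_gain > 0,
            reduction_fraction > 0, reduction_fraction < 1,
            bubble_delay_s < control_end_s,
            control_end_s < total_duration_s,
            burst_length_s > 0, burst_interval_s >= burst_length_s,
            n_targets >= 1, baseline_duration_s > 0)
  if (is.null(h_setpoint_db)) h_setpoint_db <- mean(goal_band_db)
  structure(
    list(p_start_w = p_start_w, p_max_w = p_max_w,
         goal_band_db = goal_band_db, p_gain = p_gain,
         h_setpoint_db = h_setpoint_db,
         baseline_duration_s = baseline_duration_s,
         bubble_delay_s = bubble_delay_s, control_end_s = control_end_s,
         total_duration_s = total_duration_s,
         reduction_fraction = reduction_fraction,
         burst_length_s = burst_length_s,
         burst_interval_s = burst_interval_s,
         n_targets = as.integer(n_targets),
         k_sub = k_sub, k_bb = k_bb,
         global_freeze = isTRUE(global_freeze)),
    class = "controller_config"
  )
}

#' Per-target controller state
#'
#' @param target_index 0-based target index.
#' @param config A [controller_config()].
#' @return An object of class `target_state` with fields `target_index`,
#'   `power_w`, `phase` (`fixed_pre`, `controlling` or `frozen`),
#'   `reduced_flag` and `goal_hit_powers`.
#' @export
target_state <- function(target_index, config = controller_config()) {
  structure(
    list(target_index = as.integer(target_index),
         power_w = config$p_start_w,
         phase = "fixed_pre",
         reduced_flag = FALSE,
         goal_hit_powers = numeric(0)),
    class = "target_state"
  )
}

#' Proportional power update
#'
#' Applies one control step to a target in the `controlling` phase.  If the
#' measured harmonic enhancement `H` lies inside the goal band the power is
#' left unchanged and recorded as a goal hit.  Otherwise the update acts in
#' the pressure domain — harmonic enhancement in dB is assumed proportional
#' to pressure amplitude, and pressure to the square root of power — as a
#' relative step toward the setpoint:
#' `p <- p * (1 + p_gain * (H_set - H))`, i.e.
#' `power <- power * (1 + p_gain * (H_set - H))^2`, clamped to
#' `(0, p_max_w]`.  The multiplicative factor is floored at a small positive
#' value so a wildly high `H` cannot produce a non-physical (non-positive)
#' pressure.
#'
#' @param state A [target_state()] in phase `"controlling"`.
#' @param detection A `detection_result` from [detect_events()] (its event
#'   flags must be `FALSE`; events are handled by [safety_reduce()]).
#' @param config A [controller_config()].
#' @return The updated `target_state`.
#' @export
proportional_update <- function(state, detection, config) {
  stopifnot(inherits(state, "target_state"),
            inherits(detection, "detection_result"))
  if (state$phase != "controlling") {
    stop("proportional_update requires a target in the 'controlling' phase")
  }
  h <- detection$harmonic_enhancement_db
  if (!is.finite(h)) {
    warning("non-finite harmonic enhancement; burst skipped, power held")
    return(state)
  }
  band <- config$goal_band_db
  if (h >= band[1] && h <= band[2]) {
    state$goal_hit_powers <- c(state$goal_hit_powers, state$power_w)
    return(state)
  }
  factor <- max(1 + config$p_gain * (config$h_setpoint_db - h), 0.05)
  state$power_w <- min(state$power_w * factor^2, config$p_max_w)
  state
}

#' Safety reduction on emission-event detection
#'
#' When a subharmonic or broadband emission event is detected on a target's
#' burst, that target's power is reduced by the configured fraction (25% by
#' default) and fixed for the remainder of the sonication.  The reduction is
#' applied at most once per target: a second event on an already-reduced
#' target is a no-op, and the reduced state is terminal.
#'
#' @param state A [target_state()].
#' @param config A [controller_config()].
#' @return The updated `target_state` (frozen, `reduced_flag = TRUE`).
#' @export
safety_reduce <- function(state, config) {
  stopifnot(inherits(state, "target_state"))
  if (state$reduced_flag) return(state)
  state$power_w <- state$power_w * (1 - config$reduction_fraction)
  state$phase <- "frozen"
  state$reduced_flag <- TRUE
  state
}

#' End-of-control freeze
#'
#' When the sonication clock crosses the end of the control window the power
#' is never increased again: it is set to the arithmetic mean of the powers
#' of all bursts whose harmonic enhancement fell inside the goal band.  If
#' the goal was never achieved the current power is held (conservative
#' fallback).  The target is frozen.
#'
#' @param state A [target_state()].
#' @param config A [controller_config()].
#' @return The updated `target_state`.
#' @export
end_of_control_freeze <- function(state, config) {
  stopifnot(inherits(state, "target_state"))
  if (state$phase == "frozen") return(state)
  if (length(state$goal_hit_powers) > 0) {
    state$power_w <- mean(state$goal_hit_powers)
  }
  state$phase <- "frozen"
  state
}

#' Run a closed-loop volumetric sonication against a plant
#'
#' Simulates a full sonication: a passive baseline acquisition calibrates the
#' pre-sonication noise floor; bursts are then fired cyclically over the
#' targets at the configured interval.  Bursts before the bolus-arrival gate
#' run at the starting power and calibrate the early-burst noise floor used
#' for event thresholds.  During the control window each target's power is
#' independently modulated by [proportional_update()]; detection events
#' trigger [safety_reduce()]; at the end of the control window
#' [end_of_control_freeze()] fixes the power.  With
#' `controller_enabled = FALSE` the power is held at `fixed_power_w`
#' throughout (events are still logged but trigger no reduction),
#' reproducing an uncontrolled exposure.
#'
#' @param plant A [plant_config()], or a function
#'   `(target_index, power_w, time_s, burst_index) -> burst_spectrum`.
#' @param config A [controller_config()].
#' @param controller_enabled Logical.
#' @param fixed_power_w Power used when the controller is disabled (defaults
#'   to `p_start_w`).
#' @param seed Integer seed fixing all stochastic draws (one independent
#'   stream per target plus an ambient stream for the passive baseline).
#' @return An object of class `sonication_log`: list with elements `log`
#'   (one data-frame row per burst: `burst_index`, `time_s`, `target_index`,
#'   `power_w`, `h_db`, `subharmonic_flag`, `broadband_flag`, `phase`, and
#'   the four band powers), `summary` (per-target end-of-control powers and
#'   event counts), `floor_pre`, `floor_early`, `config`, `seed`,
#'   `controller_enabled`, and `error` (`NULL`, or a message if the plant
#'   failed mid-run and the log is partial).
#' @examples
#' log <- run_sonication(plant_noise_free(), seed = 1)
#' summary(log)
#' @export
run_sonication <- function(plant, config = controller_config(),
                           controller_enabled = TRUE,
                           fixed_power_w = NULL, seed = 1) {
  is_cfg_plant <- inherits(plant, "plant_config")
  if (!is_cfg_plant && !is.function(plant)) {
    stop("plant must be a plant_config or a function")
  }
  if (is.null(fixed_power_w)) fixed_power_w <- config$p_start_w
  nt <- config$n_targets
  streams <- rng_streams(seed, nt + 1L,
                         names = c(paste0("target", seq_len(nt) - 1L),
                                   "ambient"))
  fire <- function(target, power, time, burst) {
    if (is_cfg_plant) {
      plant_respond(target, power, time, plant,
                    stream = streams[[target + 1L]], burst_index = burst)
    } else {
      plant(target, power, time, burst)
    }
  }

  # passive baseline: pre-sonication noise floor
  n_base <- max(2L, floor(config$baseline_duration_s / config$burst_interval_s))
  baseline <- lapply(seq_len(n_base), function(i) {
    if (is_cfg_plant) {
      plant_respond(0L, 0, 0, plant, stream = streams[["ambient"]],
                    burst_index = -i)
    } else {
      plant(0L, 0, 0, -i)
    }
  })
  floor_pre <- calibrate_noise_floor(baseline, source = "pre_sonication")

  states <- lapply(seq_len(nt) - 1L, target_state, config = config)
  n_bursts <- floor(config$total_duration_s / config$burst_interval_s)
  early <- vector("list", n_bursts)
  n_early <- 0L
  floor_early <- NULL

  rows <- vector("list", n_bursts)
  err <- NULL

  for (k in seq_len(n_bursts) - 1L) {
    t <- k * config$burst_interval_s
    tgt <- k %% nt
    st <- states[[tgt + 1L]]

    # phase transitions keyed on the sonication clock
    if (controller_enabled) {
      if (st$phase == "fixed_pre" && t >= config$bubble_delay_s) {
        st$phase <- "controlling"
      }
      if (st$phase == "controlling" && t >= config$control_end_s) {
        st <- end_of_control_freeze(st, config)
      }
    }
    power <- if (controller_enabled) st$power_w else fixed_power_w

    sp <- tryCatch(fire(tgt, power, t, k), error = function(e) e)
    if (inherits(sp, "error")) {
      err <- conditionMessage(sp)
      rows <- rows[seq_len(k)]
      break
    }

    if (t < config$bubble_delay_s) {
      n_early <- n_early + 1L
      early[[n_early]] <- sp
      det <- NULL
    } else {
      if (is.null(floor_early)) {
        floor_early <- calibrate_noise_floor(early[seq_len(n_early)],
                                             source = "early_burst")
      }
      det <- detect_events(sp, floor_early, floor_pre,
                           k_sub = config$k_sub, k_bb = config$k_bb)
    }

    rows[[k + 1L]] <- data.frame(
      burst_index = k, time_s = t, target_index = tgt, power_w = power,
      h_db = if (is.null(det)) NA_real_ else det$harmonic_enhancement_db,
      subharmonic_flag = if (is.null(det)) FALSE else det$subharmonic_flag,
      broadband_flag = if (is.null(det)) FALSE else det$broadband_flag,
      phase = st$phase,
      subharmonic_db = sp$band_power_db[["subharmonic"]],
      harmonic2_db = sp$band_power_db[["harmonic2"]],
      harmonic3_db = sp$band_power_db[["harmonic3"]],
      broadband_db = sp$band_power_db[["broadband"]],
      stringsAsFactors = FALSE
    )

    if (controller_enabled && !is.null(det)) {
      if (det$subharmonic_flag || det$broadband_flag) {
        if (config$global_freeze) {
          states <- lapply(states, safety_reduce, config = config)
          st <- states[[tgt + 1L]]
        } else {
          st <- safety_reduce(st, config)
        }
      } else if (st$phase == "controlling") {
        st <- proportional_update(st, det, config)
      }
    }
    states[[tgt + 1L]] <- st
  }

  log <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- structure(
    list(log = log,
         summary = .summarise_sonication(log, states, config),
         floor_pre = floor_pre, floor_early = floor_early,
         config = config, seed = seed,
         controller_enabled = controller_enabled,
         error = err),
    class = "sonication_log"
  )
  out
}

.summarise_sonication <- function(log, states, config) {
  per_target <- data.frame(
    target_index = vapply(states, function(s) s$target_index, integer(1)),
    end_power_w = vapply(states, function(s) s$power_w, numeric(1)),
    phase = vapply(states, function(s) s$phase, character(1)),
    reduced = vapply(states, function(s) s$reduced_flag, logical(1)),
    n_goal_hits = vapply(states, function(s) length(s$goal_hit_powers),
                         integer(1))
  )
  list(
    per_target = per_target,
    n_bursts = nrow(log),
    n_subharmonic_events = sum(log$subharmonic_flag),
    n_broadband_events = sum(log$broadband_flag),
    event_fraction = mean(log$subharmonic_flag | log$broadband_flag),
    max_power_w = max(log$power_w),
    mean_h_frozen_db = {
      sel <- log$time_s >= config$control_end_s & is.finite(log$h_db)
      if (any(sel)) mean(log$h_db[sel]) else NA_real_
    }
  )
}

#' @export
print.sonication_log <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sonication_log> %d bursts over %d targets (seed %s, controller %s)\n",
              s$n_bursts, x$config$n_targets, format(x$seed),
              if (x$controller_enabled) "on" else "off"))
  cat(sprintf("  max power: %.3f W | events: %d subharmonic, %d broadband (%.2f%% of bursts)\n",
              s$max_power_w, s$n_subharmonic_events, s$n_broadband_events,
              100 * s$event_fraction))
  if (is.finite(s$mean_h_frozen_db)) {
    cat(sprintf("  mean H in frozen phase: %.2f dB (goal %.1f-%.1f dB)\n",
                s$mean_h_frozen_db, x$config$goal_band_db[1],
                x$config$goal_band_db[2]))
  }
  if (!is.null(x$error)) cat("  PARTIAL RUN, plant error: ", x$error, "\n")
  invisible(x)
}

#' @export
summary.sonication_log <- function(object, ...) {
  c(object$summary,
    list(end_powers = object$summary$per_target$end_power_w))
}
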