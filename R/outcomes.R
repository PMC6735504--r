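# Treatment-outcome analysis: tumor growth kinetics, Kaplan-Meier survival,
# log-rank tests, lognormal-appropriate concentration summaries, and
# dose/exposure conversion utilities.

#' Fit a tumor volume doubling time
#'
#' Fits exponential growth `V(t) = V0 * 2^(t / Td)` to a volume series by
#' nonlinear least squares (Levenberg-Marquardt) with a log-linear warm
#' start.  For noise-free exponential data the fit is exact.  Zero or
#' negative growth yields a non-finite doubling time, returned with
#' `finite = FALSE` rather than an error.
#'
#' @param times_days Measurement times in days, strictly increasing.
#' @param volumes_mm3 Positive tumor volumes, same length (>= 3 points).
#' @param refine If `TRUE` (default) refine the log-linear estimate by
#'   nonlinear least squares on the original volume scale.
#' @return List with `doubling_days`, `v0`, `rmse` (volume scale),
#'   `finite`.
#' @examples
#' fit_doubling_time(c(0, 3, 6, 9), c(1, 2, 4, 8))$doubling_days  # 3
#' @export
fit_doubling_time <- function(times_days, volumes_mm3, refine = TRUE) {
  stopifnot(length(times_days) == length(volumes_mm3))
  if (length(times_days) < 3) stop("at least 3 points are required")
  if (any(diff(times_days) <= 0)) stop("times must be strictly increasing")
  if (any(volumes_mm3 <= 0)) stop("volumes must be positive")
  # log-linear warm start: log2(V) = log2(V0) + t / Td
  lin <- stats::lm(log2(volumes_mm3) ~ times_days)
  slope <- stats::coef(lin)[["times_days"]]
  if (!is.finite(slope) || slope <= .Machine$double.eps) {
    return(list(doubling_days = Inf, v0 = exp(mean(log(volumes_mm3))),
                rmse = NA_real_, finite = FALSE))
  }
  td <- 1 / slope
  v0 <- 2^stats::coef(lin)[["(Intercept)"]]
  if (refine) {
    fit <- tryCatch(
      minpack.lm::nlsLM(volumes_mm3 ~ v0p * 2^(times_days / tdp),
                        start = list(v0p = v0, tdp = td),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      if (is.finite(co[["tdp"]]) && co[["tdp"]] > 0) {
        td <- co[["tdp"]]
        v0 <- co[["v0p"]]
      }
    }
  }
  pred <- v0 * 2^(times_days / td)
  list(doubling_days = td, v0 = v0,
       rmse = sqrt(mean((volumes_mm3 - pred)^2)), finite = is.finite(td))
}

#' Kaplan-Meier survival curve and median survival
#'
#' Product-limit estimator (via \pkg{survival}) with the standard tie
#' handling (deaths precede censorings at equal times).  Two median
#' conventions are exposed: `"midpoint"` (the default, as in
#' `survival::survfit`) averages the times bracketing a flat stretch when the
#' curve hits 0.5 exactly — with an even number of uncensored subjects this
#' gives the mean of the two middle order statistics; `"first_leq"` returns
#' the earliest event time at which the survival estimate is <= 0.5.
#'
#' @param time_days Follow-up times.
#' @param event 1 = death/euthanasia, 0 = right-censored.
#' @param median_convention `"midpoint"` or `"first_leq"`.
#' @return List with `time`, `surv` (step function values after each event
#'   time), `n_risk`, `n_event`, `median` and `median_alt` (the other
#'   convention), and the underlying `survfit` object.
#' @examples
#' km_curve(c(23, 24, 25, 26, 27), rep(1, 5))$median  # 25
#' @export
km_curve <- function(time_days, event,
                     median_convention = c("midpoint", "first_leq")) {
  median_convention <- match.arg(median_convention)
  stopifnot(length(time_days) == length(event),
            all(time_days > 0), all(event %in% c(0, 1)))
  if (sum(event) < 1) {
    warning("all observations censored; median survival undefined")
  }
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1)
  med_mid <- unname(summary(fit)$table["median"])
  ev <- fit$n.event > 0
  med_first <- {
    hits <- fit$time[ev & fit$surv <= 0.5]
    if (length(hits)) min(hits) else NA_real_
  }
  med <- if (median_convention == "midpoint") med_mid else med_first
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med,
       median_alt = if (median_convention == "midpoint") med_first else med_mid,
       survfit = fit)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank chi-square test (via
#' \pkg{survival}), with an optional exact label-permutation reference
#' distribution for small samples.
#'
#' @param time_days Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Group labels (>= 2 levels).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations when `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return List with `chisq`, `df`, `p`, `method` (and `n_perm` when
#'   permutation-based).
#' @export
logrank_test <- function(time_days, event, group,
                         method = c("chisq", "permutation"),
                         n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("at least two groups are required")
  if (sum(event) < 1) stop("at least one event is required")
  sd0 <- survival::survdiff(survival::Surv(time_days, event) ~ group)
  df <- nlevels(group) - 1L
  if (method == "chisq") {
    return(list(chisq = sd0$chisq, df = df,
                p = stats::pchisq(sd0$chisq, df, lower.tail = FALSE),
                method = "chisq"))
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  obs <- sd0$chisq
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- sample(group)
    stat <- survival::survdiff(survival::Surv(time_days, event) ~ g)$chisq
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  list(chisq = obs, df = df, p = (hits + 1) / (n_perm + 1),
       method = "permutation", n_perm = n_perm)
}

#' Percent increase in median survival time
#'
#' `100 * (treated / reference - 1)`, the IST statistic used to compare
#' median survivals between treatment groups.
#'
#' @param median_treated,median_reference Median survivals (reference > 0).
#' @return Percent increase.
#' @examples
#' increase_in_survival_time(41.5, 25)  # 66
#' @export
increase_in_survival_time <- function(median_treated, median_reference) {
  stopifnot(median_reference > 0)
  100 * (median_treated / median_reference - 1)
}

#' Geometric mean and geometric percent CV
#'
#' Lognormal-appropriate summary for concentration data: the geometric mean
#' is `exp(mean(log(x)))` and the geometric %CV is
#' `100 * sqrt(exp(var(log(x))) - 1)` with the sample variance of the logs.
#'
#' @param values Positive numeric values.
#' @return List with `geometric_mean`, `geometric_cv_percent`, `n`.
#' @examples
#' geometric_summary(c(1, 100))$geometric_mean  # 10
#' @export
geometric_summary <- function(values) {
  if (any(values <= 0)) stop("all values must be positive")
  lx <- log(values)
  gcv <- if (length(values) >= 2) {
    100 * sqrt(exp(stats::var(lx)) - 1)
  } else {
    NA_real_
  }
  list(geometric_mean = exp(mean(lx)), geometric_cv_percent = gcv,
       n = length(values))
}

#' Paired two-tailed t-test on log-transformed data
#'
#' The comparison used for sonicated-versus-control concentration pairs:
#' a paired t-test of `log(x) - log(y)`.  Degenerate zero-variance
#' differences (a perfectly constant ratio) are flagged instead of producing
#' an unstable statistic.
#'
#' @param x,y Positive paired samples of equal length (n >= 2).
#' @return List with `t`, `df`, `p`, `mean_log_ratio`, `degenerate`.
#' @export
paired_log_ttest <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("at least 2 pairs are required")
  if (any(x <= 0) || any(y <= 0)) stop("values must be positive")
  d <- log(x) - log(y)
  if (stats::var(d) < .Machine$double.eps) {
    # identical pairs: no difference and no variance -> t = 0, p = 1;
    # a perfectly constant non-unit ratio has no valid t statistic
    if (abs(mean(d)) < sqrt(.Machine$double.eps)) {
      return(list(t = 0, df = length(d) - 1L, p = 1,
                  mean_log_ratio = 0, degenerate = FALSE))
    }
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_log_ratio = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_log_ratio = mean(d), degenerate = FALSE)
}

#' Human equivalent dose by body-surface-area scaling
#'
#' `mg/m^2 = mg/kg * Km`; the rat-to-human conversion factor Km is 6, so a
#' 50 mg/kg rat dose corresponds to a human equivalent dose of 300 mg/m^2.
#'
#' @param animal_dose_mg_per_kg Dose in mg/kg (>= 0).
#' @param km_factor Species conversion factor.
#' @return Dose in mg/m^2.
#' @examples
#' human_equivalent_dose(50, 6)  # 300
#' @export
human_equivalent_dose <- function(animal_dose_mg_per_kg, km_factor = 6) {
  stopifnot(animal_dose_mg_per_kg >= 0, km_factor > 0)
  animal_dose_mg_per_kg * km_factor
}

#' Per-target pulse repetition frequency
#'
#' With bursts interleaved over `n_targets` at `burst_interval_s`, each
#' target is revisited every `n_targets * burst_interval_s` seconds; 9
#' targets at 101.6 ms give 1.09 Hz (reported as 1.1 Hz).
#'
#' @param n_targets Number of interleaved targets.
#' @param burst_interval_s Interval between consecutive bursts, s.
#' @return PRF in Hz.
#' @examples
#' per_target_prf(9, 0.1016)
#' @export
per_target_prf <- function(n_targets, burst_interval_s) {
  stopifnot(n_targets > 0, burst_interval_s > 0)
  1 / (n_targets * burst_interval_s)
}

#' Simulate noisy exponential tumor growth
#'
#' Generates a volume series `V(t) = V0 * 2^(t / Td)` with multiplicative
#' lognormal noise, emulating weekly volumetric MRI of an exponentially
#' growing tumor.
#'
#' @param doubling_days True doubling time.
#' @param v0 Initial volume, mm^3.
#' @param times_days Measurement times.
#' @param noise_cv Lognormal coefficient of variation of the measurement
#'   noise (e.g. 0.1 for 10%).
#' @param seed Integer seed.
#' @return Data frame with `times_days` and `volumes_mm3`.
#' @export
simulate_growth_series <- function(doubling_days = 3.5, v0 = 5,
                                   times_days = seq(0, 21, by = 3.5),
                                   noise_cv = 0.1, seed = 1) {
  stopifnot(doubling_days > 0, v0 > 0)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  v <- v0 * 2^(times_days / doubling_days) *
    stats::rlnorm(length(times_days), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  data.frame(times_days = times_days, volumes_mm3 = v)
}

#' Simulate a right-censored survival table
#'
#' Draws lognormal survival times per group with administrative censoring,
#' emulating the per-subject time/event records of a survival study.
#'
#' @param n Subjects per group (recycled over `groups`).
#' @param groups Group labels.
#' @param median_days True median survival per group.
#' @param sdlog Lognormal shape.
#' @param censor_days Administrative censoring horizon (Inf = none).
#' @param seed Integer seed.
#' @return Data frame with `subject_id`, `group`, `time_days`, `event`.
#' @export
simulate_survival_table <- function(n = 6, groups = c("control", "treated"),
                                    median_days = c(25, 41.5), sdlog = 0.15,
                                    censor_days = Inf, seed = 1) {
  stopifnot(length(median_days) == length(groups))
  n <- rep_len(n, length(groups))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_along(groups), function(i) {
    t_true <- stats::rlnorm(n[i], meanlog = log(median_days[i]), sdlog = sdlog)
    t_obs <- pmin(t_true, censor_days)
    data.frame(subject_id = paste0(groups[i], "_", seq_len(n[i])),
               group = groups[i], time_days = t_obs,
               event = as.integer(t_true <= censor_days),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
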