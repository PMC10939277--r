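#' Population specification for the generative observer model
#'
#' Collects the population-level parameters of the generative perceptual
#' model. The core mechanism is incomplete flow parsing: when the observer
#' experiences visual self-motion opposite to the ball, a fraction
#' (`bias_mean`, default 20%) of the nominal self-motion speed is wrongly
#' attributed to the ball, inflating its perceived speed. Perceived ball speed
#' carries multiplicative Weber noise (`weber_speed_mean`, default 10%, with a
#' 1.5% between-participant SD), and that noise is inflated by a factor
#' `1 + precision effect` (default 20%) under opposite-direction self-motion.
#' The occluded distance is perceived with a fixed 5% Weber fraction. By
#' default no bias or precision effect applies to the same-direction or static
#' profiles, but same-direction population parameters can be set for
#' sensitivity analyses and parameter fitting.
#'
#' The self-motion speed that scales the bias is the profile's *time-averaged*
#' speed (3.6 m/s for the default ramped profile), not the 4 m/s peak.
#'
#' @param bias_mean,bias_sd mean and between-participant SD of the
#'   opposite-direction accuracy effect, as a fraction of the nominal
#'   self-motion speed.
#' @param precision_effect_mean,precision_effect_sd mean and SD of the
#'   opposite-direction precision effect (fractional inflation of the speed
#'   Weber fraction).
#' @param bias_same_mean,bias_same_sd,precision_same_mean,precision_same_sd
#'   same-direction analogues (all default 0).
#' @param weber_speed_mean,weber_speed_sd Weber fraction for ball-speed
#'   estimation (draws truncated above 0.01 when `weber_speed_sd > 0`).
#' @param weber_distance Weber fraction for occluded-distance estimation,
#'   fixed across participants.
#' @param nominal_self_speed nominal (time-averaged) self-motion speed in m/s.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(bias_mean = 0.20, bias_sd = 0.30,
                            precision_effect_mean = 0.20,
                            precision_effect_sd = 0.30,
                            bias_same_mean = 0, bias_same_sd = 0,
                            precision_same_mean = 0, precision_same_sd = 0,
                            weber_speed_mean = 0.10, weber_speed_sd = 0.015,
                            weber_distance = 0.05,
                            nominal_self_speed = 3.6) {
  args <- as.list(environment())
  if (!all(vapply(args, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    stop("all population parameters must be finite scalars", call. = FALSE)
  }
  if (bias_sd < 0 || precision_effect_sd < 0 || bias_same_sd < 0 ||
      precision_same_sd < 0 || weber_speed_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (weber_distance < 0) stop("`weber_distance` must be non-negative", call. = FALSE)
  structure(args, class = "population_spec")
}

#' A population with every self-motion effect switched off
#'
#' Convenience wrapper for null-calibration runs: all bias and precision
#' effect means and SDs are zero; the Weber noise structure is untouched.
#'
#' @param ... overrides passed on to [population_spec()].
#' @export
null_population_spec <- function(...) {
  population_spec(bias_mean = 0, bias_sd = 0,
                  precision_effect_mean = 0, precision_effect_sd = 0, ...)
}

# truncated-normal draw by resampling; when sd == 0 the mean is returned
# untouched so that noise-free configurations stay exactly noise-free
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Draw simulated observers from a population
#'
#' Independent Gaussian draws per parameter with the population means and SDs;
#' speed Weber fractions are truncated above 0.01 and precision effects above
#' -0.9. Uses R's global RNG stream (`set.seed()` for reproducibility).
#'
#' @param pop a [population_spec()].
#' @param n number of observers.
#' @return a tibble with one row per observer: `participant_id`,
#'   `bias_opposite`, `bias_same`, `precision_opposite`, `precision_same`,
#'   `weber_speed`, `weber_distance`.
#' @export
draw_observers <- function(pop, n) {
  stopifnot(inherits(pop, "population_spec"), n >= 1)
  tibble::tibble(
    participant_id = seq_len(n),
    bias_opposite = stats::rnorm(n, pop$bias_mean, pop$bias_sd),
    bias_same = stats::rnorm(n, pop$bias_same_mean, pop$bias_same_sd),
    precision_opposite = rnorm_trunc(n, pop$precision_effect_mean,
                                     pop$precision_effect_sd, -0.9),
    precision_same = rnorm_trunc(n, pop$precision_same_mean,
                                 pop$precision_same_sd, -0.9),
    weber_speed = rnorm_trunc(n, pop$weber_speed_mean, pop$weber_speed_sd, 0.01),
    weber_distance = rep(pop$weber_distance, n)
  )
}

# profile-wise bias / precision lookups (vectorised over profile)
bias_for_profile <- function(profile, bias_same, bias_opposite) {
  out <- numeric(length(profile))
  out[profile == "same"] <- bias_same[profile == "same"]
  out[profile == "opposite"] <- bias_opposite[profile == "opposite"]
  out
}

precision_for_profile <- function(profile, prec_same, prec_opposite) {
  out <- numeric(length(profile))
  out[profile == "same"] <- prec_same[profile == "same"]
  out[profile == "opposite"] <- prec_opposite[profile == "opposite"]
  out
}

# multiplicative-noise percept draw with a 0.1 m/s floor enforced by
# resampling (per-sample; noise-free means are floored directly). The noise
# magnitude scales with |mean|: an extreme bias draw can push a percept mean
# below zero, and the Weber SD must stay a valid scale parameter there.
draw_percept_speed <- function(mean_speed, sd_speed, floor = 0.1) {
  n <- length(mean_speed)
  sd_speed <- abs(sd_speed)
  noisefree <- sd_speed == 0
  x <- numeric(n)
  x[noisefree] <- pmax(mean_speed[noisefree], floor)
  # when the floor sits more than 8 SDs above the mean, resampling is
  # hopeless; the floor itself is the only mass the truncation leaves
  hopeless <- !noisefree & (mean_speed + 8 * sd_speed <= floor)
  x[hopeless] <- floor
  idx <- which(!noisefree & !hopeless)
  if (length(idx) > 0) {
    x[idx] <- stats::rnorm(length(idx), mean_speed[idx], sd_speed[idx])
    bad <- idx[x[idx] <= floor]
    while (length(bad) > 0) {
      x[bad] <- stats::rnorm(length(bad), mean_speed[bad], sd_speed[bad])
      bad <- bad[x[bad] <= floor]
    }
  }
  x
}

#' Sample a perceived ball speed
#'
#' One draw from the perceptual model: the mean perceived speed is the
#' physical speed plus the profile's bias times the nominal self-motion speed
#' (no bias for a static observer), and the SD is the observer's speed Weber
#' fraction times that mean, inflated by `1 + precision effect` for the
#' profile. Samples are resampled until above 0.1 m/s.
#'
#' @param v_ball physical ball speed in m/s (> 0).
#' @param profile a [self_motion_profile()] or one of `"static"`, `"same"`,
#'   `"opposite"`.
#' @param observer one row of [draw_observers()].
#' @param nominal_self_speed nominal self-motion speed scaling the bias.
#' @param n number of samples.
#' @return numeric vector of perceived speeds in m/s.
#' @export
perceived_speed_sample <- function(v_ball, profile, observer,
                                   nominal_self_speed = 3.6, n = 1) {
  if (any(v_ball <= 0)) stop("`v_ball` must be positive", call. = FALSE)
  dir <- if (inherits(profile, "self_motion_profile")) profile$direction else profile
  dir <- match.arg(dir, c("static", "same", "opposite"))
  b <- switch(dir, static = 0, same = observer$bias_same,
              opposite = observer$bias_opposite)
  pr <- switch(dir, static = 0, same = observer$precision_same,
               opposite = observer$precision_opposite)
  m <- v_ball + b * nominal_self_speed
  s <- observer$weber_speed * m * (1 + pr)
  draw_percept_speed(rep(m, n), rep(s, n))
}

#' Simulate one prediction-task trial
#'
#' The observer watches the ball for the visible window, forms a noisy
#' percept of its speed (biased under self-motion) and of the occluded
#' distance (5% Weber fraction), and presses the button after the extrapolated
#' time `d_perceived / v_perceived`.
#'
#' @param geom a [trial_geometry()].
#' @param profile a [self_motion_profile()] or profile direction string.
#' @param observer one row of [draw_observers()].
#' @param pop a [population_spec()] (supplies the nominal self-motion speed).
#' @return one-row tibble with the trial record, including the latent
#'   percepts (`v_perceived_mps`, `d_perceived_m`) and the signed timing error
#'   `error_s = response_s - occlusion_s`.
#' @export
simulate_prediction_trial <- function(geom, profile, observer, pop) {
  stopifnot(inherits(geom, "trial_geometry"), inherits(pop, "population_spec"))
  dir <- if (inherits(profile, "self_motion_profile")) profile$direction else profile
  v_perc <- perceived_speed_sample(geom$ball_speed, dir, observer,
                                   pop$nominal_self_speed)
  d <- geom$occluded_distance
  d_perc <- if (pop$weber_distance == 0) d else {
    x <- stats::rnorm(1, d, pop$weber_distance * d)
    while (x <= 0) x <- stats::rnorm(1, d, pop$weber_distance * d)
    x
  }
  response <- d_perc / v_perc
  tibble::tibble(
    participant_id = observer$participant_id,
    ball_speed_mps = geom$ball_speed,
    motion_profile = dir,
    occlusion_s = geom$occlusion_duration,
    v_perceived_mps = v_perc,
    d_perceived_m = d_perc,
    response_s = response,
    error_s = response - geom$occlusion_duration
  )
}

#' Prediction-task design
#'
#' Full factorial design of the motion-extrapolation experiment: for every
#' participant, `repetitions` trials in each cell of ball speed x motion
#' profile x main occlusion duration, plus (optionally) a static-only set of
#' extra occlusion durations used to map variability against occlusion time.
#'
#' @param n_participants number of participants.
#' @param repetitions repetitions per condition cell.
#' @param ball_speeds ball speeds in m/s.
#' @param occlusions main occlusion durations in seconds (all profiles).
#' @param extra_occlusions static-only occlusion durations; `NULL` drops the
#'   extra set (as in the power analysis, which uses the main design only).
#' @param profiles motion profiles.
#' @return an object of class `prediction_design`.
#' @export
prediction_design <- function(n_participants, repetitions = 13,
                              ball_speeds = c(4, 5, 6),
                              occlusions = c(0.5, 0.6, 0.7),
                              extra_occlusions = c(0.1, 0.2, 0.3, 0.4, 0.8, 0.9, 1.0),
                              profiles = c("static", "same", "opposite")) {
  if (n_participants < 1 || repetitions < 1) {
    stop("`n_participants` and `repetitions` must be at least 1", call. = FALSE)
  }
  if (length(ball_speeds) == 0 || length(occlusions) == 0 || length(profiles) == 0) {
    stop("design cells must be non-empty", call. = FALSE)
  }
  structure(
    list(n_participants = n_participants, repetitions = repetitions,
         ball_speeds = ball_speeds, occlusions = occlusions,
         extra_occlusions = extra_occlusions, profiles = profiles),
    class = "prediction_design"
  )
}

prediction_design_cells <- function(design) {
  main <- tidyr::expand_grid(
    ball_speed_mps = design$ball_speeds,
    motion_profile = design$profiles,
    occlusion_s = design$occlusions
  )
  if (length(design$extra_occlusions) > 0 && "static" %in% design$profiles) {
    extra <- tidyr::expand_grid(
      ball_speed_mps = design$ball_speeds,
      motion_profile = "static",
      occlusion_s = design$extra_occlusions
    )
    main <- dplyr::bind_rows(main, extra)
  }
  main
}

#' Simulate a full prediction-task experiment
#'
#' Vectorised generation of every trial in the design for a cohort of
#' observers drawn from (or supplied for) the population. The response model
#' is identical to [simulate_prediction_trial()].
#'
#' @param design a [prediction_design()].
#' @param pop a [population_spec()].
#' @param observers optional tibble from [draw_observers()]; drawn afresh when
#'   `NULL`. Must have `design$n_participants` rows.
#' @return tibble of trials (one row each), columns as in
#'   [simulate_prediction_trial()].
#' @export
simulate_prediction_experiment <- function(design, pop, observers = NULL) {
  stopifnot(inherits(design, "prediction_design"), inherits(pop, "population_spec"))
  if (is.null(observers)) observers <- draw_observers(pop, design$n_participants)
  stopifnot(nrow(observers) == design$n_participants)
  cells <- prediction_design_cells(design)
  trials <- tidyr::expand_grid(
    participant_id = observers$participant_id,
    cells,
    rep = seq_len(design$repetitions)
  )
  trials <- dplyr::left_join(trials, observers, by = "participant_id")
  b <- bias_for_profile(trials$motion_profile, trials$bias_same, trials$bias_opposite)
  pr <- precision_for_profile(trials$motion_profile, trials$precision_same,
                              trials$precision_opposite)
  v_mean <- trials$ball_speed_mps + b * pop$nominal_self_speed
  v_sd <- trials$weber_speed * v_mean * (1 + pr)
  v_perc <- draw_percept_speed(v_mean, v_sd)
  d <- trials$occlusion_s * trials$ball_speed_mps
  d_sd <- trials$weber_distance * d
  d_perc <- if (all(d_sd == 0)) d else {
    x <- stats::rnorm(length(d), d, d_sd)
    bad <- which(x <= 0)
    while (length(bad) > 0) {
      x[bad] <- stats::rnorm(length(bad), d[bad], d_sd[bad])
      bad <- bad[x[bad] <= 0]
    }
    x
  }
  response <- d_perc / v_perc
  tibble::tibble(
    participant_id = trials$participant_id,
    ball_speed_mps = trials$ball_speed_mps,
    motion_profile = trials$motion_profile,
    occlusion_s = trials$occlusion_s,
    v_perceived_mps = v_perc,
    d_perceived_m = d_perc,
    response_s = response,
    error_s = response - trials$occlusion_s
  )
}

#' Simulate one two-interval forced-choice speed trial
#'
#' The observer compares a noisy percept of the single ball's speed (biased
#' under self-motion) against a noisy percept of the ball-cloud speed. The
#' cloud interval involves no self-motion, so its percept carries only the
#' observer's baseline speed Weber noise. Ties are broken by a fair coin.
#'
#' @param v_ball single-ball speed in m/s.
#' @param cloud_speed comparison (ball-cloud) speed in m/s.
#' @param profile self-motion profile of the single-ball interval.
#' @param observer one row of [draw_observers()].
#' @param pop a [population_spec()].
#' @return one-row tibble with `chose_cloud` (`TRUE` when the cloud was judged
#'   faster).
#' @export
simulate_2ifc_trial <- function(v_ball, cloud_speed, profile, observer, pop) {
  dir <- if (inherits(profile, "self_motion_profile")) profile$direction else profile
  ball_perc <- perceived_speed_sample(v_ball, dir, observer, pop$nominal_self_speed)
  cloud_perc <- draw_percept_speed(cloud_speed, observer$weber_speed * cloud_speed)
  chose <- if (cloud_perc == ball_perc) stats::runif(1) < 0.5 else cloud_perc > ball_perc
  tibble::tibble(
    participant_id = observer$participant_id,
    ball_speed_mps = v_ball,
    motion_profile = dir,
    cloud_speed_mps = cloud_speed,
    chose_cloud = chose
  )
}

#' Write trial tables to CSV
#'
#' Serialise a prediction-task or speed-estimation trial table with the
#' package's stable column layout.
#'
#' @param trials a trial tibble from the simulators.
#' @param path output file path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}
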