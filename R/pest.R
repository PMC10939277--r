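#' Configuration of one modified-PEST staircase
#'
#' The two-interval speed-estimation task drives the comparison (ball-cloud)
#' speed with a modified PEST staircase. Two staircases per condition bracket
#' the point of subjective equality: one starts 30% above the single-ball
#' speed, the other 30% below. The nominal initial step is 0.6 m/s, but for
#' the first ten trials the applied step is fixed at twice that (1.2 m/s) to
#' spread the sampled levels and stabilise JND estimates. A staircase stops at
#' `max_trials` (37), or as soon as at least `min_trials` (30) have been run
#' and the internal step size has dropped below `stop_step` (0.03 m/s).
#' Levels are clipped to `[reference/3, 3 * reference]`.
#'
#' @param reference_speed single-ball speed in m/s.
#' @param start_offset fractional start offset, +0.30 or -0.30.
#' @param initial_step nominal PEST step in m/s.
#' @param early_step step applied on the first `early_trial_count` trials.
#' @param early_trial_count number of fixed-step early trials.
#' @param min_trials,max_trials termination window.
#' @param stop_step step-size stopping threshold in m/s.
#' @param lower_bound,upper_bound level limits in m/s.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(reference_speed, start_offset = 0.30,
                             initial_step = 0.6, early_step = 1.2,
                             early_trial_count = 10,
                             min_trials = 30, max_trials = 37,
                             stop_step = 0.03,
                             lower_bound = reference_speed / 3,
                             upper_bound = 3 * reference_speed) {
  if (reference_speed <= 0) stop("`reference_speed` must be positive", call. = FALSE)
  if (lower_bound >= upper_bound) stop("bounds must satisfy lower < upper", call. = FALSE)
  if (min_trials > max_trials) stop("`min_trials` must not exceed `max_trials`", call. = FALSE)
  if (stop_step >= initial_step) stop("`stop_step` must be below `initial_step`", call. = FALSE)
  start <- reference_speed * (1 + start_offset)
  if (start < lower_bound || start > upper_bound) {
    stop("start level lies outside the staircase bounds", call. = FALSE)
  }
  structure(
    list(reference_speed = reference_speed, start_offset = start_offset,
         initial_step = initial_step, early_step = early_step,
         early_trial_count = early_trial_count,
         min_trials = min_trials, max_trials = max_trials,
         stop_step = stop_step,
         lower_bound = lower_bound, upper_bound = upper_bound),
    class = "staircase_config"
  )
}

#' Initialise a staircase
#'
#' @param config a [staircase_config()].
#' @return an object of class `staircase_state` positioned at the start level
#'   (`reference * (1 + start_offset)`), with the internal PEST step at
#'   `initial_step` and no trials run.
#' @export
init_staircase <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(
      config = config,
      current_level = config$reference_speed * (1 + config$start_offset),
      current_step = config$initial_step,
      n_trials = 0L,
      last_direction = "none",
      steps_same_direction = 0L,
      last_step_was_double = FALSE,
      double_deferred = FALSE,
      terminated = FALSE,
      levels = numeric(config$max_trials),
      responses = logical(config$max_trials),
      applied_steps = numeric(config$max_trials)
    ),
    class = "staircase_state"
  )
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(
    "<staircase_state> ref=%g m/s trials=%d level=%.3f step=%.4f %s\n",
    x$config$reference_speed, x$n_trials, x$current_level, x$current_step,
    if (x$terminated) "(terminated)" else ""
  ))
  invisible(x)
}

#' Advance a staircase by one response
#'
#' Records the response given at the current level, applies the step rules,
#' and moves the level. The staircase targets the 50% point of a PSE task:
#' "cloud judged faster" steps the comparison level down, otherwise up.
#'
#' Step-size rules (classic sequential-testing heuristics): on a reversal the
#' step halves; the third and subsequent same-direction steps double, except
#' that when the most recent reversal immediately followed a doubled step the
#' doubling is deferred to the fourth same-direction step. During the first
#' `early_trial_count` trials the applied step is overridden to `early_step`
#' and the internal step is left untouched; rule bookkeeping starts fresh on
#' the following trial, with the last early-phase direction remembered only
#' for reversal detection.
#'
#' @param state a `staircase_state`.
#' @param response logical; `TRUE` when the comparison (cloud) was judged
#'   faster.
#' @return the updated `staircase_state`.
#' @export
update_staircase <- function(state, response) {
  if (state$terminated) stop("cannot update a terminated staircase", call. = FALSE)
  if (!is.logical(response) || length(response) != 1 || is.na(response)) {
    stop("`response` must be TRUE or FALSE", call. = FALSE)
  }
  cfg <- state$config
  n <- state$n_trials + 1L
  direction <- if (response) "down" else "up"
  state$levels[n] <- state$current_level
  state$responses[n] <- response

  if (n <= cfg$early_trial_count) {
    applied <- cfg$early_step
    state$last_direction <- direction
    state$steps_same_direction <- 1L # rules restart after the early phase
  } else {
    if (state$last_direction == "none") {
      state$steps_same_direction <- 1L
    } else if (direction == state$last_direction) {
      state$steps_same_direction <- state$steps_same_direction + 1L
    } else {
      state$current_step <- state$current_step / 2
      state$double_deferred <- state$last_step_was_double
      state$steps_same_direction <- 1L
    }
    threshold <- if (state$double_deferred) 4L else 3L
    if (state$steps_same_direction >= threshold) {
      state$current_step <- state$current_step * 2
      state$last_step_was_double <- TRUE
    } else {
      state$last_step_was_double <- FALSE
    }
    state$last_direction <- direction
    applied <- state$current_step
  }
  state$applied_steps[n] <- applied

  delta <- if (direction == "down") -applied else applied
  state$current_level <- min(max(state$current_level + delta, cfg$lower_bound),
                             cfg$upper_bound)
  state$n_trials <- n
  if (n >= cfg$max_trials ||
      (n >= cfg$min_trials && state$current_step < cfg$stop_step)) {
    state$terminated <- TRUE
  }
  state
}

# hot-loop runner shared by run_staircase and the simulators: the same state
# machine as update_staircase() unrolled onto scalar locals (the stateful API
# costs ~20x more per trial); equivalence with the stateful path is enforced
# by a replay test. Returns the terminated state without the history tibble.
run_staircase_lean <- function(config, responder) {
  early_n <- config$early_trial_count
  early_step <- config$early_step
  min_n <- config$min_trials
  max_n <- config$max_trials
  stop_step <- config$stop_step
  lo <- config$lower_bound
  hi <- config$upper_bound
  level <- config$reference_speed * (1 + config$start_offset)
  step <- config$initial_step
  n <- 0L
  last_dir_down <- NA # NA = none yet
  run_len <- 0L
  last_was_double <- FALSE
  deferred <- FALSE
  levels <- numeric(max_n)
  responses <- logical(max_n)
  applied_steps <- numeric(max_n)
  repeat {
    resp <- tryCatch(
      isTRUE(responder(level)),
      error = function(e) {
        stop(sprintf("responder failed at trial %d (level %.3f m/s): %s",
                     n + 1L, level, conditionMessage(e)), call. = FALSE)
      }
    )
    n <- n + 1L
    down <- resp
    levels[n] <- level
    responses[n] <- resp
    if (n <= early_n) {
      applied <- early_step
      last_dir_down <- down
      run_len <- 1L
    } else {
      if (is.na(last_dir_down)) {
        run_len <- 1L
      } else if (down == last_dir_down) {
        run_len <- run_len + 1L
      } else {
        step <- step / 2
        deferred <- last_was_double
        run_len <- 1L
      }
      if (run_len >= (if (deferred) 4L else 3L)) {
        step <- step * 2
        last_was_double <- TRUE
      } else {
        last_was_double <- FALSE
      }
      last_dir_down <- down
      applied <- step
    }
    applied_steps[n] <- applied
    level <- level + (if (down) -applied else applied)
    if (level < lo) level <- lo else if (level > hi) level <- hi
    if (n >= max_n || (n >= min_n && step < stop_step)) break
  }
  structure(
    list(
      config = config,
      current_level = level,
      current_step = step,
      n_trials = n,
      last_direction = if (is.na(last_dir_down)) "none" else
        if (last_dir_down) "down" else "up",
      steps_same_direction = run_len,
      last_step_was_double = last_was_double,
      double_deferred = deferred,
      terminated = TRUE,
      levels = levels,
      responses = responses,
      applied_steps = applied_steps
    ),
    class = "staircase_state"
  )
}

#' Run a staircase to termination against a responder
#'
#' @param config a [staircase_config()].
#' @param responder a function of one argument (the presented level in m/s)
#'   returning `TRUE` when the comparison is judged faster. Errors raised by
#'   the responder are propagated with staircase context.
#' @return a list with `history` (tibble: `trial_index`, `level`, `response`,
#'   `applied_step`) and `state` (the terminated `staircase_state`).
#' @export
run_staircase <- function(config, responder) {
  stopifnot(is.function(responder))
  state <- run_staircase_lean(config, responder)
  idx <- seq_len(state$n_trials)
  history <- tibble::tibble(
    trial_index = idx,
    level = state$levels[idx],
    response = state$responses[idx],
    applied_step = state$applied_steps[idx]
  )
  list(history = history, state = state)
}

#' Speed-estimation experiment design
#'
#' Eighteen staircases per participant: two start offsets x three ball speeds
#' x three motion profiles, each between `min_trials` and `max_trials` trials,
#' for a total of 540 to 666 trials per participant.
#'
#' @param n_participants number of participants.
#' @param ball_speeds single-ball speeds in m/s.
#' @param profiles motion profiles.
#' @param start_offsets fractional staircase start offsets.
#' @param min_trials,max_trials staircase termination window (the power
#'   analysis also considers 20-27 and 40-47 windows for roughly 50 and 90
#'   trials per condition).
#' @return an object of class `speedest_design`.
#' @export
speedest_design <- function(n_participants, ball_speeds = c(4, 5, 6),
                            profiles = c("static", "same", "opposite"),
                            start_offsets = c(-0.30, 0.30),
                            min_trials = 30, max_trials = 37) {
  if (n_participants < 1) stop("`n_participants` must be at least 1", call. = FALSE)
  structure(
    list(n_participants = n_participants, ball_speeds = ball_speeds,
         profiles = profiles, start_offsets = start_offsets,
         min_trials = min_trials, max_trials = max_trials),
    class = "speedest_design"
  )
}

# internal: observer responder closure for one condition
observer_responder <- function(v_ball, dir, observer, pop) {
  b <- switch(dir, static = 0, same = observer$bias_same,
              opposite = observer$bias_opposite)
  pr <- switch(dir, static = 0, same = observer$precision_same,
               opposite = observer$precision_opposite)
  m <- v_ball + b * pop$nominal_self_speed
  s <- abs(observer$weber_speed * m * (1 + pr))
  w <- observer$weber_speed
  ball_hopeless <- m + 8 * s <= 0.1 # percept floor unreachable by resampling
  function(level) {
    if (ball_hopeless) {
      ball_perc <- 0.1
    } else {
      ball_perc <- m + s * stats::rnorm(1)
      while (ball_perc <= 0.1) ball_perc <- m + s * stats::rnorm(1)
    }
    cloud_perc <- level * (1 + w * stats::rnorm(1))
    while (cloud_perc <= 0.1) cloud_perc <- level * (1 + w * stats::rnorm(1))
    if (cloud_perc == ball_perc) stats::runif(1) < 0.5 else cloud_perc > ball_perc
  }
}

#' Simulate a full speed-estimation experiment
#'
#' Runs all staircases of the design for a cohort of simulated observers,
#' with each trial answered by the generative 2IFC observer model
#' (see [simulate_2ifc_trial()]).
#'
#' @param design a [speedest_design()].
#' @param pop a [population_spec()].
#' @param observers optional tibble from [draw_observers()].
#' @return tibble of trials: `participant_id`, `staircase_id`, `trial_index`,
#'   `ball_speed_mps`, `motion_profile`, `cloud_speed_mps`, `chose_cloud`.
#' @export
simulate_speedest_experiment <- function(design, pop, observers = NULL) {
  stopifnot(inherits(design, "speedest_design"), inherits(pop, "population_spec"))
  if (is.null(observers)) observers <- draw_observers(pop, design$n_participants)
  stopifnot(nrow(observers) == design$n_participants)
  combos <- tidyr::expand_grid(
    participant_id = observers$participant_id,
    ball_speed_mps = design$ball_speeds,
    motion_profile = design$profiles,
    start_offset = design$start_offsets
  )
  n_comb <- nrow(combos)
  out_p <- vector("list", n_comb); out_s <- vector("list", n_comb)
  out_t <- vector("list", n_comb); out_v <- vector("list", n_comb)
  out_m <- vector("list", n_comb); out_l <- vector("list", n_comb)
  out_c <- vector("list", n_comb)
  for (i in seq_len(n_comb)) {
    p_i <- combos$participant_id[i]
    v_i <- combos$ball_speed_mps[i]
    prof_i <- combos$motion_profile[i]
    off_i <- combos$start_offset[i]
    obs <- observers[observers$participant_id == p_i, ]
    cfg <- staircase_config(v_i, off_i,
                            min_trials = design$min_trials,
                            max_trials = design$max_trials)
    res <- run_staircase_lean(cfg, observer_responder(v_i, prof_i, obs, pop))
    n_i <- res$n_trials
    out_p[[i]] <- rep(p_i, n_i)
    out_s[[i]] <- rep(sprintf("p%03d_v%g_%s_%s", p_i, v_i, prof_i,
                              if (off_i > 0) "hi" else "lo"), n_i)
    out_t[[i]] <- seq_len(n_i)
    out_v[[i]] <- rep(v_i, n_i)
    out_m[[i]] <- rep(prof_i, n_i)
    out_l[[i]] <- res$levels[seq_len(n_i)]
    out_c[[i]] <- res$responses[seq_len(n_i)]
  }
  tibble::tibble(
    participant_id = unlist(out_p),
    staircase_id = unlist(out_s),
    trial_index = unlist(out_t),
    ball_speed_mps = unlist(out_v),
    motion_profile = unlist(out_m),
    cloud_speed_mps = unlist(out_l),
    chose_cloud = unlist(out_c)
  )
}
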