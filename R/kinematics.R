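#' Self-motion velocity profile
#'
#' Describes the visually simulated lateral self-motion of the observer during
#' the 0.5 s in which the ball is visible: speed ramps up over the first
#' `ramp_duration` seconds, stays at `peak_speed` for `steady_duration`, and
#' ramps back down over the final `ramp_duration`. The default ramp shape is a
#' (truncated, rescaled) Gaussian CDF, time-symmetric so that each ramp
#' contributes exactly `peak_speed / 2` on average; with the defaults the
#' observer therefore covers 1.8 m in 0.5 s at a time-averaged speed of
#' 3.6 m/s. A linear ramp is available for sensitivity checks.
#'
#' @param direction one of `"static"`, `"same"`, `"opposite"` — the direction
#'   of self-motion relative to the ball's travel direction.
#' @param peak_speed peak self-motion speed in m/s.
#' @param ramp_duration duration of each speed ramp in seconds.
#' @param steady_duration duration of the constant-speed phase in seconds.
#' @param ramp_shape `"gaussian_cdf"` (default) or `"linear"`.
#' @return an object of class `self_motion_profile`.
#' @examples
#' pr <- self_motion_profile("opposite")
#' self_speed_at(pr, 0.25)            # 4 m/s during the steady phase
#' observer_displacement(pr, 0, 0.5)  # -1.8 m (opposite the ball direction)
#' @export
self_motion_profile <- function(direction = c("static", "same", "opposite"),
                                peak_speed = 4.0,
                                ramp_duration = 0.05,
                                steady_duration = 0.40,
                                ramp_shape = c("gaussian_cdf", "linear")) {
  direction <- match.arg(direction)
  ramp_shape <- match.arg(ramp_shape)
  if (!is.numeric(peak_speed) || peak_speed < 0) {
    stop("`peak_speed` must be a non-negative number", call. = FALSE)
  }
  if (ramp_duration < 0 || steady_duration < 0) {
    stop("profile durations must be non-negative", call. = FALSE)
  }
  structure(
    list(
      direction = direction,
      peak_speed = peak_speed,
      ramp_duration = ramp_duration,
      steady_duration = steady_duration,
      total_duration = 2 * ramp_duration + steady_duration,
      ramp_shape = ramp_shape
    ),
    class = "self_motion_profile"
  )
}

#' @export
print.self_motion_profile <- function(x, ...) {
  cat(sprintf(
    "<self_motion_profile> direction=%s peak=%g m/s ramps=%g s steady=%g s (%s ramp)\n",
    x$direction, x$peak_speed, x$ramp_duration, x$steady_duration, x$ramp_shape
  ))
  invisible(x)
}

# signed axis convention: +1 points in the ball's travel direction
profile_sign <- function(profile) {
  switch(profile$direction, static = 0, same = 1, opposite = -1)
}

# Gaussian-CDF ramp, truncated at +-3 sd and rescaled to hit 0 and 1 exactly.
# Symmetric about the ramp midpoint, so its mean value is exactly 1/2.
ramp_shape_value <- function(u, shape) {
  lo <- stats::pnorm(-3)
  hi <- stats::pnorm(3)
  switch(shape,
    gaussian_cdf = (stats::pnorm((u - 0.5) * 6) - lo) / (hi - lo),
    linear = u
  )
}

# closed-form integral of the ramp shape from 0 to u (u in [0, 1])
ramp_shape_integral <- function(u, shape) {
  if (shape == "linear") return(u^2 / 2)
  lo <- stats::pnorm(-3)
  hi <- stats::pnorm(3)
  g <- function(z) (z - 0.5) * stats::pnorm((z - 0.5) * 6) +
    stats::dnorm((z - 0.5) * 6) / 6
  (g(u) - g(0) - lo * u) / (hi - lo)
}

#' Instantaneous self-motion speed
#'
#' Unsigned speed of the observer at time `t`; 0 outside `[0, total_duration]`
#' and for static profiles. Vectorised over `t`.
#'
#' @param profile a [self_motion_profile()].
#' @param t time in seconds (any real; vectorised).
#' @return speed in m/s.
#' @export
self_speed_at <- function(profile, t) {
  stopifnot(inherits(profile, "self_motion_profile"))
  if (profile$direction == "static") return(rep(0, length(t)))
  r <- profile$ramp_duration
  total <- profile$total_duration
  pk <- profile$peak_speed
  out <- numeric(length(t))
  inside <- t > 0 & t < total
  tt <- t[inside]
  s <- rep(pk, length(tt))
  if (r > 0) {
    up <- tt < r
    dn <- tt > total - r
    s[up] <- pk * ramp_shape_value(tt[up] / r, profile$ramp_shape)
    s[dn] <- pk * ramp_shape_value((total - tt[dn]) / r, profile$ramp_shape)
  }
  out[inside] <- s
  out
}

# unsigned displacement from time 0 to t (t clipped into [0, total])
displacement_from_zero <- function(profile, t) {
  r <- profile$ramp_duration
  total <- profile$total_duration
  pk <- profile$peak_speed
  t <- pmin(pmax(t, 0), total)
  vapply(t, function(u) {
    if (u <= r) {
      if (r == 0) return(pk * u)
      pk * r * ramp_shape_integral(u / r, profile$ramp_shape)
    } else if (u <= total - r) {
      pk * r / 2 + pk * (u - r)
    } else {
      full <- pk * r / 2 + pk * profile$steady_duration
      tail <- pk * r / 2 -
        (if (r == 0) 0 else pk * r * ramp_shape_integral((total - u) / r, profile$ramp_shape))
      full + tail
    }
  }, numeric(1))
}

#' Signed observer displacement over a time interval
#'
#' Integral of the self-motion speed from `t0` to `t1`, signed along the axis
#' that points in the ball's travel direction (positive for `"same"`, negative
#' for `"opposite"`, zero for `"static"`). Uses the closed-form integral of the
#' ramp shape, so the default profile's full-interval displacement is exactly
#' `peak_speed * (ramp_duration + steady_duration)` = 1.8 m in magnitude.
#'
#' @inheritParams self_speed_at
#' @param t0,t1 interval endpoints in seconds, `t0 <= t1`.
#' @return signed displacement in metres.
#' @export
observer_displacement <- function(profile, t0, t1) {
  stopifnot(inherits(profile, "self_motion_profile"))
  if (t0 > t1) stop("`t0` must not exceed `t1`", call. = FALSE)
  if (profile$direction == "static") return(0)
  profile_sign(profile) *
    (displacement_from_zero(profile, t1) - displacement_from_zero(profile, t0))
}

#' Occluded target distance
#'
#' Distance between the point where the ball disappears and the target
#' rectangle: the plain product of occlusion duration and ball speed.
#'
#' @param occlusion_duration occlusion duration in seconds (> 0).
#' @param ball_speed ball speed in m/s (> 0).
#' @return distance in metres.
#' @examples
#' target_distance(0.6, 5) # 3 m
#' @export
target_distance <- function(occlusion_duration, ball_speed) {
  if (any(occlusion_duration <= 0) || any(ball_speed <= 0)) {
    stop("`occlusion_duration` and `ball_speed` must be positive", call. = FALSE)
  }
  occlusion_duration * ball_speed
}

#' Trial geometry
#'
#' Deterministic geometry of one trial: a ball of the given speed crosses the
#' observer's field of view at `depth` metres, visible for `visible_duration`
#' seconds with the visible path centred on the observer's starting
#' straight-ahead direction, then travels occluded for `occlusion_duration`
#' until it reaches the target.
#'
#' @param ball_speed ball speed in m/s.
#' @param occlusion_duration occlusion duration in seconds.
#' @param ball_direction `"right"` or `"left"`.
#' @param depth lateral track depth in metres (default 8).
#' @param visible_duration visible part of the trajectory in seconds.
#' @return an object of class `trial_geometry` with the occluded distance
#'   precomputed.
#' @export
trial_geometry <- function(ball_speed, occlusion_duration,
                           ball_direction = c("right", "left"),
                           depth = 8.0, visible_duration = 0.5) {
  ball_direction <- match.arg(ball_direction)
  if (depth <= 0 || visible_duration <= 0) {
    stop("`depth` and `visible_duration` must be positive", call. = FALSE)
  }
  structure(
    list(
      ball_speed = ball_speed,
      ball_direction = ball_direction,
      depth = depth,
      visible_duration = visible_duration,
      occlusion_duration = occlusion_duration,
      occluded_distance = target_distance(occlusion_duration, ball_speed)
    ),
    class = "trial_geometry"
  )
}

#' Retinal trace of the visible trajectory
#'
#' Signed eccentricity of the ball relative to the translating observer's
#' (fixed) straight-ahead direction, and its angular speed, on a uniform time
#' grid over the visible window. The observer translates but does not rotate
#' (matching the fixation instruction), so the angle is
#' `atan(relative lateral offset / depth)`. Angular speed is obtained by
#' central differences on the grid (one-sided at the ends).
#'
#' @param geom a [trial_geometry()].
#' @param profile a [self_motion_profile()].
#' @param dt grid step in seconds (must be positive and at most 0.005).
#' @return a tibble with columns `time_s`, `angle_deg`, `angular_speed_degps`.
#' @export
retinal_trace <- function(geom, profile, dt = 1e-3) {
  stopifnot(inherits(geom, "trial_geometry"), inherits(profile, "self_motion_profile"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (dt > 0.005) stop("`dt` must be at most 0.005 s", call. = FALSE)
  T <- geom$visible_duration
  times <- seq(0, T, by = dt)
  if (times[length(times)] < T) times <- c(times, T)
  mirror <- if (geom$ball_direction == "left") -1 else 1
  # ball-axis coordinates: +x is the ball's travel direction
  x_ball <- -geom$ball_speed * T / 2 + geom$ball_speed * times
  x_obs <- profile_sign(profile) * displacement_from_zero(profile, times)
  angle <- mirror * atan((x_ball - x_obs) / geom$depth) * 180 / pi
  n <- length(times)
  dadt <- numeric(n)
  dadt[2:(n - 1)] <- (angle[3:n] - angle[1:(n - 2)]) /
    (times[3:n] - times[1:(n - 2)])
  dadt[1] <- (angle[2] - angle[1]) / (times[2] - times[1])
  dadt[n] <- (angle[n] - angle[n - 1]) / (times[n] - times[n - 1])
  tibble::tibble(time_s = times, angle_deg = angle, angular_speed_degps = dadt)
}

#' Mean absolute retinal speed over the visible window
#'
#' Time-average (trapezoidal) of the absolute angular speed of the ball across
#' the visible trajectory, for a given self-motion profile. For a static
#' observer and constant ball speed this equals the closed form
#' `2 * atan(v * T / (2 * depth)) / T`.
#'
#' Note: summary figures of mean retinal speed for stimuli of this kind are
#' convention-dependent (averaging window, reference frame, eccentricity
#' handling), so tables computed with other conventions need not agree with
#' these values. This function follows strictly from the clean geometry
#' above — about 28.5 deg/s for a static observer and a 4 m/s ball — and the
#' ordering across motion profiles (opposite > static > same) holds under any
#' convention.
#'
#' @inheritParams retinal_trace
#' @return mean absolute angular speed in deg/s.
#' @export
mean_abs_retinal_speed <- function(geom, profile, dt = 1e-3) {
  tr <- retinal_trace(geom, profile, dt)
  y <- abs(tr$angular_speed_degps)
  t <- tr$time_s
  n <- length(t)
  sum((y[-1] + y[-n]) / 2 * diff(t)) / (t[n] - t[1])
}

#' Mean absolute retinal speed table
#'
#' The 3 x 3 table of mean absolute retinal speeds (motion profile x ball
#' speed) implied by the clean trial geometry, in the long CSV-ready layout
#' `profile, ball_speed_mps, mean_abs_retinal_speed_degps`.
#'
#' @param ball_speeds ball speeds in m/s.
#' @param dt grid step passed to [mean_abs_retinal_speed()].
#' @return a tibble with one row per profile x speed.
#' @export
retinal_speed_table <- function(ball_speeds = c(4, 5, 6), dt = 1e-3) {
  grid <- tidyr::expand_grid(
    profile = c("static", "same", "opposite"),
    ball_speed_mps = ball_speeds
  )
  grid$mean_abs_retinal_speed_degps <- purrr::map2_dbl(
    grid$profile, grid$ball_speed_mps,
    function(pr, v) {
      mean_abs_retinal_speed(
        trial_geometry(v, occlusion_duration = 0.5),
        self_motion_profile(pr),
        dt = dt
      )
    }
  )
  grid
}
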