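#' Observed self-motion difference summaries
#'
#' Per-participant condition differences between a self-motion profile and the
#' static baseline, which are the targets of the simulation-based fit. For the
#' prediction task these are mean timing-error and SD differences per ball
#' speed x occlusion duration cell; for the speed-estimation task PSE and JND
#' differences per ball speed.
#'
#' @param x for `task = "prediction"` a single participant's (filtered) trial
#'   table; for `task = "speed_estimation"` a single participant's
#'   psychometric fit table.
#' @param direction `"opposite"` or `"same"`.
#' @param task which task the summary belongs to.
#' @return a tibble of per-cell differences (`mean_diff` and `sd_diff`, in
#'   seconds or m/s depending on the task).
#' @export
summarize_differences <- function(x, direction = c("opposite", "same"),
                                  task = c("prediction", "speed_estimation")) {
  direction <- match.arg(direction)
  task <- match.arg(task)
  if (task == "prediction") {
    d <- x[x$motion_profile %in% c("static", direction), , drop = FALSE]
    cells <- d |>
      dplyr::group_by(.data$ball_speed_mps, .data$occlusion_s, .data$motion_profile) |>
      dplyr::summarise(m = mean(.data$error_s), s = stats::sd(.data$error_s),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "motion_profile", values_from = c("m", "s"))
    need <- c(paste0("m_", direction), "m_static")
    if (!all(need %in% names(cells)) || anyNA(cells[need])) {
      stop("static or self-motion cells missing for this participant", call. = FALSE)
    }
    tibble::tibble(
      ball_speed_mps = cells$ball_speed_mps,
      occlusion_s = cells$occlusion_s,
      mean_diff = cells[[paste0("m_", direction)]] - cells$m_static,
      sd_diff = cells[[paste0("s_", direction)]] - cells$s_static
    )
  } else {
    d <- x[x$motion_profile %in% c("static", direction), , drop = FALSE]
    wide <- d |>
      dplyr::group_by(.data$ball_speed_mps, .data$motion_profile) |>
      dplyr::summarise(pse = mean(.data$pse_mps), jnd = mean(.data$jnd_mps),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "motion_profile", values_from = c("pse", "jnd"))
    need <- c(paste0("pse_", direction), "pse_static")
    if (!all(need %in% names(wide)) || anyNA(wide[need])) {
      stop("static or self-motion cells missing for this participant", call. = FALSE)
    }
    tibble::tibble(
      ball_speed_mps = wide$ball_speed_mps,
      mean_diff = wide[[paste0("pse_", direction)]] - wide$pse_static,
      sd_diff = wide[[paste0("jnd_", direction)]] - wide$jnd_static
    )
  }
}

# root median squared error across condition cells
rmedse <- function(sim, obs) sqrt(stats::median((sim - obs)^2))

# ---- prediction-task objective -------------------------------------------
#
# Common-random-numbers simulator: all standard-normal deviates are drawn
# once per optimisation and reused for every candidate parameter value, so
# the Monte Carlo objective is smooth in the parameter and a Brent-style
# scalar search is well-posed. The percept floor is applied as a hard clamp
# here (instead of resampling) to keep the objective deterministic in the
# candidate value; it binds with negligible probability at realistic
# parameters.
build_prediction_objective <- function(trials, direction, pop, n_sim) {
  cells <- trials[trials$motion_profile %in% c("static", direction), , drop = FALSE] |>
    dplyr::count(.data$motion_profile, .data$ball_speed_mps, .data$occlusion_s)
  dir_cells <- cells[cells$motion_profile == direction, , drop = FALSE]
  sta_cells <- cells[cells$motion_profile == "static", , drop = FALSE]
  key <- function(d) paste(d$ball_speed_mps, d$occlusion_s)
  common <- intersect(key(dir_cells), key(sta_cells))
  if (length(common) == 0) stop("no common cells between profiles", call. = FALSE)
  dir_cells <- dir_cells[key(dir_cells) %in% common, , drop = FALSE]
  sta_cells <- sta_cells[key(sta_cells) %in% common, , drop = FALSE]
  dir_cells <- dir_cells[order(key(dir_cells)), ]
  sta_cells <- sta_cells[order(key(sta_cells)), ]
  n_cells <- nrow(dir_cells)

  expand <- function(celltab) {
    idx <- rep(seq_len(n_cells), celltab$n)          # per-trial cell id
    n_t <- length(idx)
    list(
      v = rep(celltab$ball_speed_mps, celltab$n),
      occ = rep(celltab$occlusion_s, celltab$n),
      d = rep(celltab$ball_speed_mps * celltab$occlusion_s, celltab$n),
      group = rep(idx, n_sim) + rep((seq_len(n_sim) - 1) * n_cells, each = n_t),
      n_t = n_t
    )
  }
  dd <- expand(dir_cells)
  ss <- expand(sta_cells)
  # common random numbers, drawn once
  z <- list(
    v_dir = stats::rnorm(n_sim * dd$n_t), d_dir = stats::rnorm(n_sim * dd$n_t),
    v_sta = stats::rnorm(n_sim * ss$n_t), d_sta = stats::rnorm(n_sim * ss$n_t)
  )
  w <- pop$weber_speed_mean
  wd <- pop$weber_distance
  nominal <- pop$nominal_self_speed
  cnt_dir <- rep(dir_cells$n, n_sim)
  cnt_sta <- rep(sta_cells$n, n_sim)

  cell_errors <- function(ex, zv, zd, bias, noise_mult) {
    v_mean <- rep(ex$v, n_sim) + bias * nominal
    v_perc <- pmax(v_mean * (1 + w * noise_mult * zv), 0.1)
    d_perc <- rep(ex$d, n_sim) * (1 + wd * zd)
    err <- d_perc / v_perc - rep(ex$occ, n_sim)
    list(
      m = rowsum(err, ex$group)[, 1],
      ss = rowsum(err^2, ex$group)[, 1]
    )
  }
  moments <- function(agg, cnt) {
    m <- agg$m / cnt
    s <- sqrt(pmax(agg$ss - cnt * m^2, 0) / pmax(cnt - 1, 1))
    list(mean = m, sd = s)
  }

  function(accuracy, precision, target = c("mean", "sd"), observed) {
    target <- match.arg(target)
    md <- moments(cell_errors(dd, z$v_dir, z$d_dir, accuracy, 1 + precision), cnt_dir)
    ms <- moments(cell_errors(ss, z$v_sta, z$d_sta, 0, 1), cnt_sta)
    sim <- if (target == "mean") md$mean - ms$mean else md$sd - ms$sd
    per_dataset <- vapply(seq_len(n_sim), function(i) {
      rows <- ((i - 1) * n_cells + 1):(i * n_cells)
      rmedse(sim[rows], observed)
    }, numeric(1))
    stats::median(per_dataset)
  }
}

#' Two-step fit of self-motion effects, prediction task
#'
#' Simulation-based estimation of one participant's accuracy and precision
#' effects of self-motion on perceived speed (as fractions of the nominal
#' self-motion speed). Step one sets the precision effect to zero and fits
#' the accuracy parameter on the mean timing-error differences (profile minus
#' static, per speed x occlusion cell); step two fixes the accuracy parameter
#' and fits the precision effect on the SD differences. Each objective is the
#' median across `n_sim` simulated datasets of the root median squared error
#' between simulated and observed cell differences, minimised by Brent's
#' method (`stats::optimize`) over [-1, 1] for accuracy and (-0.9, 3] for
#' precision, with common random numbers across candidate values.
#'
#' @param trials one participant's filtered prediction-task trials.
#' @param direction `"opposite"` or `"same"`.
#' @param pop a [population_spec()] supplying the Weber fractions and nominal
#'   self-motion speed used by the simulator.
#' @param n_sim simulated datasets per objective evaluation (default 50).
#' @param fit_precision set `FALSE` to skip step two.
#' @param tol optimiser tolerance on the parameter scale.
#' @return one-row tibble: `accuracy_param`, `precision_param`,
#'   `objective_accuracy`, `objective_precision`, `n_sim_datasets`.
#' @export
fit_prediction_effects <- function(trials, direction = c("opposite", "same"),
                                   pop = population_spec(), n_sim = 50,
                                   fit_precision = TRUE, tol = 1e-3) {
  direction <- match.arg(direction)
  if (n_sim < 25) stop("`n_sim` must be at least 25", call. = FALSE)
  obs <- summarize_differences(trials, direction, "prediction")
  obs <- obs[order(paste(obs$ball_speed_mps, obs$occlusion_s)), ]
  objective <- build_prediction_objective(trials, direction, pop, n_sim)
  f_acc <- function(a) objective(a, 0, "mean", obs$mean_diff)
  opt_a <- stats::optimize(f_acc, c(-1, 1), tol = tol)
  if (!is.finite(opt_a$objective)) stop("non-finite accuracy objective", call. = FALSE)
  a_hat <- opt_a$minimum
  p_hat <- NA_real_
  obj_p <- NA_real_
  if (fit_precision) {
    f_prec <- function(p) objective(a_hat, p, "sd", obs$sd_diff)
    opt_p <- stats::optimize(f_prec, c(-0.9, 3), tol = tol)
    if (!is.finite(opt_p$objective)) stop("non-finite precision objective", call. = FALSE)
    p_hat <- opt_p$minimum
    obj_p <- opt_p$objective
  }
  tibble::tibble(accuracy_param = a_hat, precision_param = p_hat,
                 objective_accuracy = opt_a$objective,
                 objective_precision = obj_p, n_sim_datasets = n_sim)
}

# ---- speed-estimation objective ------------------------------------------
#
# Staircase-level CRN simulator: one matrix of ball-percept and cloud-percept
# deviates per simulated dataset/staircase/trial, reused across candidates.
build_speedest_objective <- function(speeds, direction, pop, n_sim,
                                     min_trials, max_trials) {
  n_stair <- length(speeds) * 2 * 2 # speed x profile(dir, static) x start
  z_ball <- array(stats::rnorm(n_sim * n_stair * max_trials),
                  dim = c(n_sim, n_stair, max_trials))
  z_cloud <- array(stats::rnorm(n_sim * n_stair * max_trials),
                   dim = c(n_sim, n_stair, max_trials))
  grid <- tidyr::expand_grid(speed = speeds, profile = c(direction, "static"),
                             start = c(-0.30, 0.30))
  w <- pop$weber_speed_mean
  nominal <- pop$nominal_self_speed

  cfgs <- lapply(seq_len(nrow(grid)), function(k) {
    staircase_config(grid$speed[k], grid$start[k],
                     min_trials = min_trials, max_trials = max_trials)
  })
  # staircase pairs (the two start offsets) pooled per speed x profile cell
  cell_key <- paste(grid$speed, grid$profile)
  cells <- unique(cell_key)
  use_mean <- function(target) target == "mean"

  function(accuracy, precision, target = c("mean", "sd"), observed) {
    target <- match.arg(target)
    per_dataset <- vapply(seq_len(n_sim), function(i) {
      lev <- vector("list", nrow(grid))
      cho <- vector("list", nrow(grid))
      for (k in seq_len(nrow(grid))) {
        is_dir <- grid$profile[k] == direction
        m_ball <- grid$speed[k] + if (is_dir) accuracy * nominal else 0
        s_ball <- w * m_ball * (1 + if (is_dir) precision else 0)
        zb <- z_ball[i, k, ]
        zc <- z_cloud[i, k, ]
        t_idx <- 0L
        st <- run_staircase_lean(cfgs[[k]], function(level) {
          t_idx <<- t_idx + 1L
          ball <- max(m_ball + s_ball * zb[t_idx], 0.1)
          cloud <- max(level * (1 + w * zc[t_idx]), 0.1)
          cloud > ball
        })
        idx <- seq_len(st$n_trials)
        lev[[k]] <- st$levels[idx]
        cho[[k]] <- st$responses[idx]
      }
      # one quick-start ML fit per pooled cell
      vals <- vapply(cells, function(ck) {
        ks <- which(cell_key == ck)
        x <- unlist(lev[ks])
        y <- unlist(cho[ks])
        f <- fit_cumulative_gaussian(x, y,
                                     starts = list(c(mean(x), 0.75 * stats::sd(x))))
        if (use_mean(target)) f$pse else f$jnd
      }, numeric(1))
      names(vals) <- cells
      sim_diff <- vapply(seq_along(speeds), function(j) {
        vals[[paste(speeds[j], direction)]] - vals[[paste(speeds[j], "static")]]
      }, numeric(1))
      keep <- is.finite(sim_diff) & is.finite(observed)
      if (!any(keep)) return(NA_real_)
      rmedse(sim_diff[keep], observed[keep])
    }, numeric(1))
    stats::median(per_dataset, na.rm = TRUE)
  }
}

#' Two-step fit of self-motion effects, speed-estimation task
#'
#' Same procedure as [fit_prediction_effects()], with fitted PSE differences
#' (profile minus static, per ball speed) as the accuracy target and JND
#' differences as the precision target. Each objective evaluation simulates
#' `n_sim` complete staircase datasets (both profiles, both start offsets)
#' with common random numbers and refits psychometric functions to them.
#'
#' @param fits one participant's psychometric fit table (converged rows are
#'   used).
#' @inheritParams fit_prediction_effects
#' @param n_sim simulated datasets per objective evaluation (default 25).
#' @param min_trials,max_trials staircase termination window used by the
#'   simulator.
#' @export
fit_speedest_effects <- function(fits, direction = c("opposite", "same"),
                                 pop = population_spec(), n_sim = 25,
                                 min_trials = 30, max_trials = 37,
                                 fit_precision = TRUE, tol = 1e-3) {
  direction <- match.arg(direction)
  if (n_sim < 25) stop("`n_sim` must be at least 25", call. = FALSE)
  fits <- fits[fits$converged, , drop = FALSE]
  obs <- summarize_differences(fits, direction, "speed_estimation")
  obs <- obs[order(obs$ball_speed_mps), ]
  objective <- build_speedest_objective(obs$ball_speed_mps, direction, pop,
                                        n_sim, min_trials, max_trials)
  f_acc <- function(a) objective(a, 0, "mean", obs$mean_diff)
  opt_a <- stats::optimize(f_acc, c(-1, 1), tol = tol)
  if (!is.finite(opt_a$objective)) stop("non-finite accuracy objective", call. = FALSE)
  a_hat <- opt_a$minimum
  p_hat <- NA_real_
  obj_p <- NA_real_
  if (fit_precision) {
    f_prec <- function(p) objective(a_hat, p, "sd", obs$sd_diff)
    opt_p <- stats::optimize(f_prec, c(-0.9, 3), tol = tol)
    p_hat <- opt_p$minimum
    obj_p <- opt_p$objective
  }
  tibble::tibble(accuracy_param = a_hat, precision_param = p_hat,
                 objective_accuracy = opt_a$objective,
                 objective_precision = obj_p, n_sim_datasets = n_sim)
}

#' Fit self-motion effect parameters for a whole cohort
#'
#' Runs the two-step simulation-based fit for every participant, task and
#' self-motion direction, mirroring the per-participant layout of the
#' fitted-effect tables.
#'
#' @param pred_trials filtered prediction-task trials (all participants);
#'   `NULL` skips the prediction task.
#' @param se_fits psychometric fit table (all participants); `NULL` skips the
#'   speed-estimation task.
#' @param pop a [population_spec()].
#' @param directions self-motion directions to fit.
#' @param fit_precision whether to run step two.
#' @param n_sim_prediction,n_sim_speedest simulated datasets per objective
#'   evaluation.
#' @param min_trials,max_trials staircase window for the speed-estimation
#'   simulator.
#' @return tibble: `participant_id`, `task`, `direction`, `accuracy_param`,
#'   `precision_param`, objectives and `n_sim_datasets`.
#' @export
fit_cohort_effects <- function(pred_trials = NULL, se_fits = NULL,
                               pop = population_spec(),
                               directions = c("opposite", "same"),
                               fit_precision = TRUE,
                               n_sim_prediction = 50, n_sim_speedest = 25,
                               min_trials = 30, max_trials = 37) {
  out <- list()
  if (!is.null(pred_trials)) {
    for (dir in directions) {
      rows <- pred_trials |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::group_modify(function(d, key) {
          fit_prediction_effects(d, dir, pop, n_sim_prediction, fit_precision)
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(task = "prediction", direction = dir)
      out[[length(out) + 1]] <- rows
    }
  }
  if (!is.null(se_fits)) {
    for (dir in directions) {
      rows <- se_fits |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::group_modify(function(d, key) {
          fit_speedest_effects(d, dir, pop, n_sim_speedest,
                               min_trials, max_trials, fit_precision)
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(task = "speed_estimation", direction = dir)
      out[[length(out) + 1]] <- rows
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::select("participant_id", "task", "direction", dplyr::everything())
}

#' Cross-task regression of fitted effect parameters
#'
#' Ordinary least-squares regression of the prediction-task parameters on the
#' speed-estimation parameters, separately per direction and domain
#' (accuracy, precision). When one shared generative parameter drives both
#' tasks the slope is expected near 1.
#'
#' @param effects fitted-effect table from [fit_cohort_effects()] with both
#'   tasks present for every participant.
#' @return tibble: `direction`, `domain`, `slope`, `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @export
cross_task_regression <- function(effects) {
  domains <- c(accuracy = "accuracy_param", precision = "precision_param")
  out <- list()
  for (dir in unique(effects$direction)) {
    for (dom in names(domains)) {
      col <- domains[[dom]]
      wide <- effects[effects$direction == dir, c("participant_id", "task", col)] |>
        tidyr::pivot_wider(names_from = "task", values_from = dplyr::all_of(col))
      if (!all(c("prediction", "speed_estimation") %in% names(wide))) next
      wide <- wide[stats::complete.cases(wide), , drop = FALSE]
      if (nrow(wide) < 5) next
      if (stats::sd(wide$speed_estimation) < 1e-12) {
        stop(sprintf("degenerate regressor (%s, %s): constant parameters",
                     dir, dom), call. = FALSE)
      }
      fit <- stats::lm(prediction ~ speed_estimation, data = wide)
      ci <- stats::confint(fit)["speed_estimation", ]
      out[[length(out) + 1]] <- tibble::tibble(
        direction = dir, domain = dom,
        slope = unname(stats::coef(fit)["speed_estimation"]),
        ci_low = ci[[1]], ci_high = ci[[2]],
        p_value = summary(fit)$coefficients["speed_estimation", "Pr(>|t|)"],
        n = nrow(wide)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' One-sample tests of the fitted effect parameters
#'
#' Intercept-only regression (equivalent to a one-sample t-test) of each
#' task x direction x domain cell of the fitted-effect table against zero.
#' Degenerate cells (zero variance across participants) are reported with a
#' diagnostic note instead of a p-value.
#'
#' @param effects fitted-effect table from [fit_cohort_effects()].
#' @return tibble with one row per task x direction x domain: `mean`,
#'   `p_value`, `n`, `note`.
#' @export
one_sample_tests <- function(effects) {
  long <- effects |>
    tidyr::pivot_longer(cols = c("accuracy_param", "precision_param"),
                        names_to = "domain", values_to = "value") |>
    dplyr::mutate(domain = sub("_param$", "", .data$domain)) |>
    dplyr::filter(is.finite(.data$value))
  long |>
    dplyr::group_by(.data$task, .data$direction, .data$domain) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 5) {
        return(tibble::tibble(mean = mean(d$value), p_value = NA_real_,
                              n = nrow(d), note = "fewer than 5 participants"))
      }
      if (stats::sd(d$value) < 1e-12) {
        return(tibble::tibble(mean = mean(d$value), p_value = NA_real_,
                              n = nrow(d), note = "zero variance: test refused"))
      }
      fit <- stats::lm(value ~ 1, data = d)
      tibble::tibble(mean = mean(d$value),
                     p_value = summary(fit)$coefficients[1, "Pr(>|t|)"],
                     n = nrow(d), note = "ok")
    }) |>
    dplyr::ungroup()
}
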