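#' Experiment design for power simulation
#'
#' Bundles the design knobs varied in the Monte Carlo power analysis: cohort
#' size, prediction-task repetitions per condition, and the staircase
#' termination window (30-37 trials gives roughly 70 trials per
#' speed-estimation condition from the two pooled staircases; 20-27 and 40-47
#' give roughly 50 and 90).
#'
#' @param n_participants number of participants (at least 2).
#' @param prediction_repetitions repetitions per prediction-task cell.
#' @param staircase_min_trials,staircase_max_trials staircase window.
#' @param ball_speeds,occlusions,profiles condition cells.
#' @param extra_occlusions static-only occlusion set; excluded by default in
#'   power runs (the confirmatory contrasts live in the main design).
#' @param alpha significance level.
#' @param n_simulations default Monte Carlo repetitions (250, with 100 as a
#'   documented desk-scale preset).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_participants = 40, prediction_repetitions = 13,
                        staircase_min_trials = 30, staircase_max_trials = 37,
                        ball_speeds = c(4, 5, 6),
                        occlusions = c(0.5, 0.6, 0.7),
                        extra_occlusions = NULL,
                        profiles = c("static", "same", "opposite"),
                        alpha = 0.05, n_simulations = 250) {
  if (n_participants < 2) stop("`n_participants` must be at least 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (n_simulations < 1) stop("`n_simulations` must be positive", call. = FALSE)
  structure(
    list(n_participants = n_participants,
         prediction_repetitions = prediction_repetitions,
         staircase_min_trials = staircase_min_trials,
         staircase_max_trials = staircase_max_trials,
         ball_speeds = ball_speeds, occlusions = occlusions,
         extra_occlusions = extra_occlusions, profiles = profiles,
         alpha = alpha, n_simulations = n_simulations),
    class = "design_spec"
  )
}

#' Simulate one complete experiment
#'
#' Draws a cohort of observers (shared between tasks, so that cross-task
#' correlations reflect the shared generative parameters) and simulates the
#' requested tasks at the given design.
#'
#' @param design a [design_spec()].
#' @param pop a [population_spec()].
#' @param tasks which tasks to simulate.
#' @param observers optional pre-drawn observer tibble.
#' @return list with `observers`, `prediction` (trial tibble or `NULL`) and
#'   `speed_estimation` (trial tibble or `NULL`).
#' @export
simulate_experiment <- function(design, pop,
                                tasks = c("prediction", "speed_estimation"),
                                observers = NULL) {
  stopifnot(inherits(design, "design_spec"))
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (is.null(observers)) observers <- draw_observers(pop, design$n_participants)
  pred <- NULL
  se <- NULL
  if ("prediction" %in% tasks) {
    pd <- prediction_design(design$n_participants, design$prediction_repetitions,
                            design$ball_speeds, design$occlusions,
                            design$extra_occlusions, design$profiles)
    pred <- simulate_prediction_experiment(pd, pop, observers)
  }
  if ("speed_estimation" %in% tasks) {
    sd_ <- speedest_design(design$n_participants, design$ball_speeds,
                           design$profiles,
                           min_trials = design$staircase_min_trials,
                           max_trials = design$staircase_max_trials)
    se <- simulate_speedest_experiment(sd_, pop, observers)
  }
  list(observers = observers, prediction = pred, speed_estimation = se)
}

# p-values of the six confirmatory tests on one simulated experiment.
# Power loops use the fast Wald z-test on the lme4 t-values for the fixed
# effects of Eqs. 3/6 (the bootstrap path is reserved for confirmatory
# analyses); the LRT-based tests are identical to the confirmatory path.
confirmatory_pvalues <- function(sim, tests, directions = c("opposite", "same")) {
  p <- list()
  need_pred <- any(c("H1a", "H1b", "H3a", "H3b") %in% tests)
  need_se <- any(c("H2a", "H2b", "H3a", "H3b") %in% tests)
  summaries <- NULL
  fits <- NULL
  if (need_pred) {
    kept <- filter_prediction_trials(sim$prediction)$kept
    if (any(c("H1b", "H3a", "H3b") %in% tests)) {
      summaries <- prediction_condition_summaries(kept)
    }
    if ("H1a" %in% tests) {
      res <- accuracy_lmm_prediction(kept)
      for (dir in directions) {
        term <- paste0("motion_profile", dir)
        row <- res$coefficients[res$coefficients$term == term, ]
        p[[paste0("H1a_", dir)]] <- if (nrow(row) == 1) row$p_wald[[1]] else NA_real_
      }
    }
    if ("H1b" %in% tests) {
      for (dir in directions) {
        p[[paste0("H1b_", dir)]] <- precision_lrt_prediction(summaries, dir)$p_value
      }
    }
  }
  if (need_se) {
    kept_se <- filter_staircases(sim$speed_estimation)$kept
    fits <- fit_psychometric_all(kept_se)
    if ("H2a" %in% tests) {
      res <- pse_lmm(fits)
      for (dir in directions) {
        term <- paste0("motion_profile", dir)
        row <- res$coefficients[res$coefficients$term == term, ]
        p[[paste0("H2a_", dir)]] <- if (nrow(row) == 1) row$p_wald[[1]] else NA_real_
      }
    }
    if ("H2b" %in% tests) {
      for (dir in directions) {
        p[[paste0("H2b_", dir)]] <- jnd_lrt(fits, dir)$p_value
      }
    }
  }
  if ("H3a" %in% tests) {
    for (dir in directions) {
      p[[paste0("H3a_", dir)]] <- bias_correlation(summaries, fits, dir)$p_value
    }
  }
  if ("H3b" %in% tests) {
    for (dir in directions) {
      p[[paste0("H3b_", dir)]] <- precision_link_lrt(summaries, fits, dir)$p_value
    }
  }
  unlist(p)
}

#' Monte Carlo power and false-positive-rate estimation
#'
#' Simulates complete experiments from the generative model, runs the
#' requested confirmatory tests on each, and reports per-test rejection
#' proportions at `alpha` with exact binomial 95% intervals. With the
#' generative effects set to zero the same machinery estimates the
#' false-positive rate, which should sit near `alpha`.
#'
#' @param design a [design_spec()].
#' @param pop a [population_spec()].
#' @param tests subset of `c("H1a","H1b","H2a","H2b","H3a","H3b")`:
#'   accuracy (a) and precision (b) tests for motion extrapolation (H1),
#'   speed estimation (H2) and the cross-task link (H3).
#' @param directions self-motion directions to test against static.
#' @param n_simulations number of simulated experiments.
#' @param alpha rejection level.
#' @param seed RNG seed (all simulation randomness flows from it).
#' @param progress print a dot every 10 simulations.
#' @return an object of class `power_result`: tibble of `test`, `n_ok`,
#'   `rejections`, `power`, `ci_low`, `ci_high`, with the design, alpha and
#'   failure count as attributes.
#' @export
run_power <- function(design, pop,
                      tests = c("H1a", "H1b", "H2a", "H2b", "H3a", "H3b"),
                      directions = c("opposite", "same"),
                      n_simulations = design$n_simulations,
                      alpha = design$alpha, seed = NULL, progress = FALSE) {
  stopifnot(inherits(design, "design_spec"), inherits(pop, "population_spec"))
  tests <- match.arg(tests, several.ok = TRUE)
  if (n_simulations < 1) stop("`n_simulations` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  need <- character(0)
  if (any(c("H1a", "H1b", "H3a", "H3b") %in% tests)) need <- c(need, "prediction")
  if (any(c("H2a", "H2b", "H3a", "H3b") %in% tests)) need <- c(need, "speed_estimation")
  rows <- vector("list", n_simulations)
  n_failures <- 0L
  for (i in seq_len(n_simulations)) {
    res <- tryCatch({
      sim <- simulate_experiment(design, pop, tasks = need)
      confirmatory_pvalues(sim, tests, directions)
    }, error = function(e) NULL)
    if (is.null(res)) n_failures <- n_failures + 1L else rows[[i]] <- res
    if (progress && i %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  pmat <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pmat) || nrow(pmat) == 0) stop("every simulation failed", call. = FALSE)
  out <- purrr::map_dfr(colnames(pmat), function(nm) {
    pv <- pmat[, nm]
    ok <- sum(is.finite(pv))
    rej <- sum(pv < alpha, na.rm = TRUE)
    ci <- stats::binom.test(rej, ok)$conf.int
    tibble::tibble(test = nm, n_ok = ok, rejections = rej,
                   power = rej / ok, ci_low = ci[1], ci_high = ci[2])
  })
  structure(out, class = c("power_result", class(out)),
            design = design, alpha = alpha, n_failures = n_failures)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> alpha=%g, %d failed simulations\n",
              attr(x, "alpha"), attr(x, "n_failures")))
  NextMethod()
}

#' Write power results and a run manifest
#'
#' Serialises a `power_result` to CSV alongside a small JSON manifest with
#' the design, alpha and failure count.
#'
#' @param x a `power_result`.
#' @param csv_path output CSV path.
#' @param manifest_path optional JSON manifest path.
#' @export
write_power_results <- function(x, csv_path, manifest_path = NULL) {
  stopifnot(inherits(x, "power_result"))
  utils::write.csv(as.data.frame(x), csv_path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(
      list(design = unclass(attr(x, "design")), alpha = attr(x, "alpha"),
           n_failures = attr(x, "n_failures"),
           package_version = as.character(utils::packageVersion("flowparsim"))),
      manifest_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(csv_path)
}
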