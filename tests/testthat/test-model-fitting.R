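test_that("difference summaries reproduce noise-free arithmetic", {
  pop0 <- noise_free_pop()
  obs <- make_observer(bias_opposite = 0.2, weber_speed = 0, weber_distance = 0)
  tr <- simulate_prediction_experiment(
    prediction_design(1, 2, extra_occlusions = NULL), pop0, obs)
  d <- summarize_differences(tr, "opposite", "prediction")
  expect_equal(nrow(d), 9)
  cell <- d[d$ball_speed_mps == 4 & d$occlusion_s == 0.7, ]
  expect_equal(cell$mean_diff, 2.8 / 4.72 - 0.7, tolerance = 1e-9)
  expect_equal(d$sd_diff, rep(0, 9))
  # identical conditions: all differences zero
  obs0 <- make_observer(bias_opposite = 0, weber_speed = 0, weber_distance = 0)
  tr0 <- simulate_prediction_experiment(
    prediction_design(1, 2, extra_occlusions = NULL), pop0, obs0)
  d0 <- summarize_differences(tr0, "opposite", "prediction")
  expect_true(all(abs(d0$mean_diff) < 1e-12))
  # missing static cells are an error
  expect_error(summarize_differences(tr[tr$motion_profile == "opposite", ],
                                     "opposite", "prediction"), "missing")
})

test_that("speed-estimation difference summaries take PSE and JND contrasts", {
  fits <- tidyr::expand_grid(participant_id = 1, ball_speed_mps = c(4, 5, 6),
                             motion_profile = c("static", "opposite")) |>
    dplyr::mutate(pse_mps = ball_speed_mps +
                    ifelse(motion_profile == "opposite", 0.72, 0),
                  jnd_mps = ifelse(motion_profile == "opposite", 0.6, 0.5),
                  nll = 1, n_trials = 70, converged = TRUE, message = "ok")
  d <- summarize_differences(fits, "opposite", "speed_estimation")
  expect_equal(d$mean_diff, rep(0.72, 3))
  expect_equal(d$sd_diff, rep(0.1, 3), tolerance = 1e-12)
})

test_that("the accuracy parameter is recovered and the fit is deterministic", {
  pop <- population_spec()
  obs <- make_observer(bias_opposite = 0.3, weber_speed = 0.1)
  des <- prediction_design(1, 13, extra_occlusions = NULL)
  set.seed(50)
  tr <- simulate_prediction_experiment(des, pop, obs)
  set.seed(51)
  f1 <- fit_prediction_effects(tr, "opposite", pop, n_sim = 50)
  set.seed(51)
  f2 <- fit_prediction_effects(tr, "opposite", pop, n_sim = 50)
  expect_identical(f1, f2) # common random numbers + fixed seed
  expect_equal(f1$accuracy_param, 0.3, tolerance = 0.12)
  expect_error(fit_prediction_effects(tr, "opposite", pop, n_sim = 10), "at least 25")
})

test_that("the objective is lowest near the generative value", {
  pop <- population_spec()
  obs <- make_observer(bias_opposite = 0.25, weber_speed = 0.1)
  des <- prediction_design(1, 13, extra_occlusions = NULL)
  set.seed(52)
  hits <- sapply(1:8, function(k) {
    tr <- simulate_prediction_experiment(des, pop, obs)
    obs_sum <- summarize_differences(tr, "opposite", "prediction")
    obs_sum <- obs_sum[order(paste(obs_sum$ball_speed_mps, obs_sum$occlusion_s)), ]
    objective <- flowparsim:::build_prediction_objective(tr, "opposite", pop, 50)
    at_truth <- objective(0.25, 0, "mean", obs_sum$mean_diff)
    at_truth <= objective(0.75, 0, "mean", obs_sum$mean_diff) &&
      at_truth <= objective(-0.25, 0, "mean", obs_sum$mean_diff)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the precision step runs after accuracy and respects its bounds", {
  pop <- population_spec()
  obs <- make_observer(bias_opposite = 0.2, precision_opposite = 0.5,
                       weber_speed = 0.1)
  des <- prediction_design(1, 13, extra_occlusions = NULL)
  set.seed(53)
  tr <- simulate_prediction_experiment(des, pop, obs)
  f <- fit_prediction_effects(tr, "opposite", pop, n_sim = 50)
  expect_true(f$precision_param > -0.9 && f$precision_param <= 3)
  expect_true(is.finite(f$objective_precision))
})

test_that("null effects are recovered as near-zero parameters in the mean", {
  pop <- population_spec()
  des <- prediction_design(1, 13, extra_occlusions = NULL)
  set.seed(54)
  fits <- sapply(1:10, function(k) {
    obs <- make_observer(bias_opposite = 0, weber_speed = 0.1)
    tr <- simulate_prediction_experiment(des, pop, obs)
    fit_prediction_effects(tr, "opposite", pop, n_sim = 50,
                           fit_precision = FALSE)$accuracy_param
  })
  expect_lt(abs(mean(fits)), 0.05)
})

test_that("speed-estimation accuracy fitting recovers a single participant's bias", {
  pop <- population_spec()
  obs <- make_observer(bias_opposite = 0.3, weber_speed = 0.1)
  set.seed(55)
  se <- simulate_speedest_experiment(speedest_design(1), pop, obs)
  fits <- fit_psychometric_all(se)
  f <- fit_speedest_effects(fits, "opposite", pop, fit_precision = FALSE)
  expect_equal(f$accuracy_param, 0.3, tolerance = 0.15)
})

test_that("cross-task regression scales with the shared parameter", {
  make_effects <- function(mult, seed) {
    set.seed(seed)
    bias <- rnorm(40, 0.2, 0.3)
    dplyr::bind_rows(
      tibble::tibble(participant_id = 1:40, task = "prediction",
                     direction = "opposite",
                     accuracy_param = mult * bias + rnorm(40, 0, 0.02),
                     precision_param = rnorm(40, 0, 0.1)),
      tibble::tibble(participant_id = 1:40, task = "speed_estimation",
                     direction = "opposite",
                     accuracy_param = bias + rnorm(40, 0, 0.02),
                     precision_param = rnorm(40, 0, 0.1))
    )
  }
  r1 <- cross_task_regression(make_effects(1, 60))
  acc <- r1[r1$domain == "accuracy", ]
  expect_equal(acc$slope, 1, tolerance = 0.1)
  expect_true(acc$ci_low <= 1 && acc$ci_high >= 1)
  r2 <- cross_task_regression(make_effects(2, 61))
  expect_equal(r2[r2$domain == "accuracy", ]$slope, 2, tolerance = 0.15)
  # degenerate regressor refused
  eff <- make_effects(1, 62)
  eff$accuracy_param[eff$task == "speed_estimation"] <- 0.2
  expect_error(cross_task_regression(eff), "degenerate")
})

test_that("one-sample tests lay out eight domains and flag degeneracy", {
  set.seed(63)
  eff <- tidyr::expand_grid(participant_id = 1:20,
                            task = c("prediction", "speed_estimation"),
                            direction = c("opposite", "same")) |>
    dplyr::mutate(accuracy_param = ifelse(direction == "opposite",
                                          rnorm(dplyr::n(), 0.2, 0.1),
                                          rnorm(dplyr::n(), 0, 0.1)),
                  precision_param = rnorm(dplyr::n(), 0, 0.1))
  res <- one_sample_tests(eff)
  expect_equal(nrow(res), 8)
  opp_acc <- res[res$direction == "opposite" & res$domain == "accuracy", ]
  expect_true(all(opp_acc$p_value < 0.05))
  expect_true(all(opp_acc$mean > 0))
  # constant values refuse with a note
  eff$precision_param <- 0.1
  res2 <- one_sample_tests(eff)
  expect_true(all(grepl("refused",
                        res2$note[res2$domain == "precision"])))
})
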