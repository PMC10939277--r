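make_pred_row <- function(response_s, occlusion_s, id = 1) {
  tibble::tibble(participant_id = id, ball_speed_mps = 4,
                 motion_profile = "static", occlusion_s = occlusion_s,
                 response_s = response_s, error_s = response_s - occlusion_s)
}

test_that("the response-time outlier rule uses a strict three-times cutoff", {
  trials <- dplyr::bind_rows(
    make_pred_row(1.55, 0.5), # dropped: > 3 x occlusion
    make_pred_row(1.50, 0.5), # kept: boundary is strict
    make_pred_row(0.90, 0.5), # kept
    make_pred_row(NA, 0.5)    # malformed
  )
  res <- filter_prediction_trials(trials)
  expect_equal(nrow(res$kept), 2)
  expect_equal(nrow(res$dropped), 2)
  expect_setequal(res$dropped$reason, c("response > 3 x occlusion", "malformed"))
  expect_equal(nrow(res$kept) + nrow(res$dropped), nrow(trials))
  # idempotent
  again <- filter_prediction_trials(res$kept)
  expect_identical(again$kept, res$kept)
})

test_that("the head-rotation filter only engages when bin columns exist", {
  trials <- dplyr::bind_rows(make_pred_row(0.6, 0.5), make_pred_row(0.55, 0.5))
  trials$head_bin_1 <- c(0.5, 3.0)
  trials$head_bin_2 <- c(0.2, 2.9)
  res <- filter_prediction_trials(trials)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$dropped$reason, "head rotation out of range")
  # without the columns nothing is dropped
  res2 <- filter_prediction_trials(trials[, 1:6])
  expect_equal(nrow(res2$kept), 2)
})

make_staircase_rows <- function(id, n_at_bound, n_total = 37, ref = 4) {
  lev <- c(rep(ref / 3, n_at_bound), runif(n_total - n_at_bound, ref * 0.8, ref * 1.2))
  tibble::tibble(participant_id = 1, staircase_id = id, trial_index = 1:n_total,
                 ball_speed_mps = ref, motion_profile = "static",
                 cloud_speed_mps = lev, chose_cloud = rep(c(TRUE, FALSE), length.out = n_total))
}

test_that("staircases with more than 20% boundary contact are dropped whole", {
  set.seed(40)
  trials <- dplyr::bind_rows(
    make_staircase_rows("a", 8),  # 8/37 = 21.6% -> dropped
    make_staircase_rows("b", 7),  # 7/37 = 18.9% -> kept
    make_staircase_rows("c", 0)   # kept
  )
  res <- filter_staircases(trials)
  expect_setequal(unique(res$kept$staircase_id), c("b", "c"))
  expect_equal(unique(res$dropped$staircase_id), "a")
  expect_equal(nrow(res$kept) + nrow(res$dropped), nrow(trials))
})

test_that("condition summaries flag near-zero SD cells for precision analyses", {
  set.seed(41)
  tr <- simulate_prediction_experiment(prediction_design(2, 5), population_spec())
  s <- prediction_condition_summaries(tr)
  expect_equal(nrow(s), 2 * (9 + 21 + 9 * 2)) # 48 cells per participant
  expect_true(all(s$sd_extrapolated_s >= 0, na.rm = TRUE))
  # a constant cell gets excluded
  tr0 <- simulate_prediction_experiment(prediction_design(1, 5), noise_free_pop())
  s0 <- prediction_condition_summaries(tr0)
  expect_true(all(s0$precision_excluded))
})

test_that("the accuracy model recovers the sign and null of the generative bias", {
  set.seed(42)
  pop <- population_spec(bias_sd = 0.1, weber_speed_sd = 0)
  tr <- simulate_prediction_experiment(prediction_design(20, 5, extra_occlusions = NULL), pop)
  res <- accuracy_lmm_prediction(tr)
  co <- res$coefficients
  opp <- co[co$term == "motion_profileopposite", ]
  expect_lt(opp$estimate, 0) # earlier button presses
  expect_lt(opp$p_wald, 0.001)
  expect_equal(res$n_obs, nrow(tr))
  # all-zero errors: intercept and effects vanish
  tr0 <- simulate_prediction_experiment(prediction_design(5, 3), noise_free_pop(bias_mean = 0))
  res0 <- accuracy_lmm_prediction(tr0)
  expect_true(all(abs(res0$coefficients$estimate) < 1e-9))
  # occlusion restriction drops the static-only extras
  res_main <- accuracy_lmm_prediction(tr0, occlusions = c(0.5, 0.6, 0.7))
  expect_equal(res_main$n_obs, 5 * 27 * 3) # 5 participants x 27 cells x 3 reps
})

test_that("likelihood-ratio results are ordered, non-negative and detect identical SDs", {
  set.seed(43)
  tr <- simulate_prediction_experiment(
    prediction_design(10, 8, extra_occlusions = NULL), population_spec())
  s <- prediction_condition_summaries(tr)
  for (prof in c("opposite", "same")) {
    lrt <- precision_lrt_prediction(s, prof)
    expect_gte(lrt$statistic, 0)
    expect_gte(lrt$log_lik_test, lrt$log_lik_null)
    expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  }
  # SDs copied identically across profiles within every participant x speed x
  # occlusion cell: the profile contrast is exactly zero in-sample and the
  # statistic collapses
  base <- tidyr::expand_grid(participant_id = 1:8, ball_speed_mps = c(4, 5, 6),
                             occlusion_s = c(0.5, 0.6, 0.7))
  base$sd_cell <- exp(rnorm(nrow(base), log(0.05), 0.3))
  s0 <- tidyr::expand_grid(base, motion_profile = c("static", "opposite")) |>
    dplyr::mutate(mean_extrapolated_s = occlusion_s,
                  sd_extrapolated_s = sd_cell, mean_error_s = 0,
                  n_trials = 10, precision_excluded = FALSE)
  lrt0 <- precision_lrt_prediction(s0, "opposite")
  expect_lt(lrt0$statistic, 1e-3)
})

test_that("PSE and JND models run on psychometric fits and order their likelihoods", {
  set.seed(44)
  se <- simulate_speedest_experiment(speedest_design(10), population_spec())
  fits <- fit_psychometric_all(filter_staircases(se)$kept)
  res <- pse_lmm(fits)
  opp <- res$coefficients[res$coefficients$term == "motion_profileopposite", ]
  expect_gt(opp$estimate, 0) # overestimation under opposing self-motion
  lrt <- jnd_lrt(fits, "opposite")
  expect_gte(lrt$statistic, 0)
  expect_gte(lrt$log_lik_test, lrt$log_lik_null)
})

synthetic_link_data <- function(n = 40, shared = TRUE, seed = 45) {
  set.seed(seed)
  bias <- rnorm(n, 0.2, 0.3)
  bias_pred <- if (shared) bias else rnorm(n, 0.2, 0.3)
  grid <- tidyr::expand_grid(participant_id = 1:n, ball_speed_mps = c(4, 5, 6),
                             motion_profile = c("static", "opposite"),
                             occlusion_s = c(0.5, 0.6, 0.7))
  summaries <- grid |>
    dplyr::mutate(
      mean_extrapolated_s = occlusion_s *
        ball_speed_mps / (ball_speed_mps +
                            ifelse(motion_profile == "opposite",
                                   bias_pred[participant_id] * 3.6, 0)) +
        rnorm(nrow(grid), 0, 0.005),
      sd_extrapolated_s = 0.05 + 0.02 * runif(nrow(grid)),
      mean_error_s = mean_extrapolated_s - occlusion_s,
      n_trials = 13, precision_excluded = FALSE
    )
  fits <- tidyr::expand_grid(participant_id = 1:n, ball_speed_mps = c(4, 5, 6),
                             motion_profile = c("static", "opposite")) |>
    dplyr::mutate(
      pse_mps = ball_speed_mps + ifelse(motion_profile == "opposite",
                                        bias[participant_id] * 3.6, 0) +
        rnorm(dplyr::n(), 0, 0.05),
      jnd_mps = 0.5 + rnorm(dplyr::n(), 0, 0.03),
      nll = 30, n_trials = 70, converged = TRUE, message = "ok"
    )
  list(summaries = summaries, fits = fits)
}

test_that("shared biases across tasks produce a negative cross-task slope", {
  d <- synthetic_link_data(shared = TRUE)
  res <- bias_correlation(d$summaries, d$fits, "opposite")
  expect_lt(res$slope, 0)
  expect_lt(res$ci[2], 0) # CI excludes zero
  expect_equal(res$n, 40)
})

test_that("independent biases leave the cross-task slope indistinguishable from zero", {
  hits <- sapply(1:10, function(k) {
    d <- synthetic_link_data(shared = FALSE, seed = 500 + k)
    res <- bias_correlation(d$summaries, d$fits, "opposite")
    res$ci[1] <= 0 && res$ci[2] >= 0
  })
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate cross-task inputs are refused with a diagnostic", {
  d <- synthetic_link_data()
  d$fits$pse_mps <- d$fits$ball_speed_mps # identical participants: zero spread
  expect_error(bias_correlation(d$summaries, d$fits, "opposite"), "degenerate")
  d2 <- synthetic_link_data()
  few <- d2$summaries$participant_id <= 3
  expect_error(bias_correlation(d2$summaries[few, ], d2$fits, "opposite"),
               "at least 5")
})

test_that("the precision-link LRT runs and respects likelihood ordering", {
  d <- synthetic_link_data()
  lrt <- precision_link_lrt(d$summaries, d$fits, "opposite")
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  d$fits$jnd_mps <- 0.5
  expect_error(precision_link_lrt(d$summaries, d$fits, "opposite"), "degenerate")
})

test_that("parametric bootstrap intervals are deterministic, ordered and calibrated", {
  set.seed(46)
  d <- data.frame(y = rnorm(40, 2, 1), x = rnorm(40))
  fit <- lm(y ~ x, data = d)
  ci1 <- bootstrap_ci(fit, n_boot = 300, seed = 7)
  ci2 <- bootstrap_ci(fit, n_boot = 300, seed = 7)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_low <= ci1$ci_high))
  expect_error(bootstrap_ci(fit, n_boot = 50), "at least 200")
  # constant data: zero-width interval for the intercept-only model
  fit0 <- lm(y ~ 1, data = data.frame(y = rep(3, 20)))
  ci0 <- bootstrap_ci(fit0, n_boot = 200, seed = 1)
  expect_equal(ci0$ci_low, ci0$ci_high)
  expect_equal(ci0$ci_low, 3)
  # coverage of a known slope on small linear datasets
  set.seed(47)
  hits <- sapply(1:60, function(k) {
    dd <- data.frame(x = rnorm(25))
    dd$y <- 1 + 0.5 * dd$x + rnorm(25, 0, 0.7)
    ci <- bootstrap_ci(lm(y ~ x, data = dd), n_boot = 200)
    ci$ci_low[2] <= 0.5 && ci$ci_high[2] >= 0.5
  })
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 1.0)
})

test_that("bootstrap intervals attach to mixed-model coefficients", {
  set.seed(48)
  tr <- simulate_prediction_experiment(
    prediction_design(8, 3, extra_occlusions = NULL), population_spec())
  res <- accuracy_lmm_prediction(tr, n_boot = 200, seed = 9)
  co <- res$coefficients
  expect_true(all(c("ci_low", "ci_high") %in% names(co)))
  opp <- co[co$term == "motion_profileopposite", ]
  expect_true(opp$ci_low <= opp$estimate && opp$estimate <= opp$ci_high)
})
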