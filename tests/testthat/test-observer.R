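test_that("observer draws follow the population and are reproducible", {
  pop <- population_spec()
  # zero SDs: every observer equals the means
  pop0 <- population_spec(bias_sd = 0, precision_effect_sd = 0, weber_speed_sd = 0)
  o <- draw_observers(pop0, 5)
  expect_true(all(o$bias_opposite == 0.20))
  expect_true(all(o$precision_opposite == 0.20))
  expect_true(all(o$weber_speed == 0.10))
  # large-sample moments
  set.seed(100)
  big <- draw_observers(pop, 10000)
  expect_equal(mean(big$bias_opposite), 0.20, tolerance = 0.01)
  expect_equal(sd(big$bias_opposite), 0.30, tolerance = 0.01)
  expect_true(all(big$weber_speed > 0.01))
  expect_true(all(big$precision_opposite > -0.9))
  # determinism
  set.seed(42); a <- draw_observers(pop, 10)
  set.seed(42); b <- draw_observers(pop, 10)
  expect_identical(a, b)
})

test_that("perceived speed has the stated bias and Weber noise structure", {
  obs <- make_observer(bias_opposite = 0.2, weber_speed = 0)
  expect_equal(perceived_speed_sample(4, "opposite", obs, 3.6), 4.72)
  expect_equal(perceived_speed_sample(4, "static", obs, 3.6), 4.0)
  expect_error(perceived_speed_sample(-1, "static", obs), "positive")
  # moment check: SD = weber * mean * (1 + precision)
  obs2 <- make_observer(bias_opposite = 0.2, precision_opposite = 0.2,
                        weber_speed = 0.10)
  set.seed(101)
  draws <- perceived_speed_sample(5, "opposite", obs2, 3.6, n = 10000)
  expect_equal(mean(draws), 5.72, tolerance = 0.02)
  expect_equal(sd(draws), 0.10 * 5.72 * 1.2, tolerance = 0.02 * 0.686 / 0.02)
  expect_equal(sd(draws), 0.686, tolerance = 0.686 * 0.02)
  expect_true(all(draws > 0.1))
})

test_that("noise-free prediction trials follow the extrapolation identity", {
  pop0 <- noise_free_pop()
  obs <- make_observer(weber_speed = 0, weber_distance = 0)
  static <- simulate_prediction_trial(trial_geometry(4, 0.5), "static", obs, pop0)
  expect_equal(static$response_s, 0.5, tolerance = 1e-12)
  opp <- simulate_prediction_trial(trial_geometry(4, 0.7), "opposite", obs, pop0)
  expect_equal(opp$response_s, 2.8 / 4.72, tolerance = 1e-12)
  expect_equal(opp$error_s, 2.8 / 4.72 - 0.7, tolerance = 1e-12)
  # a fitted negative same-direction bias delays the response
  obs_neg <- make_observer(bias_same = -0.06, weber_speed = 0, weber_distance = 0)
  same <- simulate_prediction_trial(trial_geometry(5, 0.6), "same", obs_neg, pop0)
  expect_gt(same$response_s, 0.6)
})

test_that("bias propagation identity holds exactly with noise off", {
  pop0 <- noise_free_pop()
  for (a in c(-0.3, 0.1, 0.45)) {
    des <- prediction_design(1, 1, extra_occlusions = NULL)
    obs <- make_observer(bias_opposite = a, weber_speed = 0, weber_distance = 0)
    tr <- simulate_prediction_experiment(des, pop0, obs)
    opp <- tr[tr$motion_profile == "opposite", ]
    expected <- opp$occlusion_s * (opp$ball_speed_mps /
                                     (opp$ball_speed_mps + a * 3.6) - 1)
    expect_equal(opp$error_s, expected, tolerance = 1e-9)
    sta <- tr[tr$motion_profile == "static", ]
    expect_equal(sta$error_s, rep(0, nrow(sta)), tolerance = 1e-12)
  }
})

test_that("experiment factorials produce the documented trial counts", {
  pop <- population_spec()
  tr5 <- simulate_prediction_experiment(prediction_design(2, 5), pop)
  counts <- table(tr5$participant_id)
  expect_true(all(counts == 240)) # 135 main + 105 static-only extras
  tr13 <- simulate_prediction_experiment(
    prediction_design(1, 13, extra_occlusions = NULL), pop)
  expect_equal(nrow(tr13), 351) # 3 speeds x 3 profiles x 3 occlusions x 13
  expect_error(prediction_design(0, 5), "at least 1")
})

test_that("extrapolated time times perceived speed returns the perceived distance", {
  set.seed(11)
  pop <- population_spec()
  tr <- simulate_prediction_experiment(prediction_design(3, 5), pop)
  expect_true(all(abs(tr$response_s * tr$v_perceived_mps - tr$d_perceived_m) <
                    1e-12 * pmax(tr$d_perceived_m, 1)))
})

test_that("response variability scales with occlusion duration", {
  # Weber-like behaviour: per-cell SD of the produced interval grows in
  # proportion to the occlusion duration at fixed parameters
  set.seed(12)
  pop <- population_spec(bias_sd = 0, precision_effect_sd = 0, weber_speed_sd = 0)
  des <- prediction_design(1, 4000, ball_speeds = 4, occlusions = c(0.5, 1.0),
                           extra_occlusions = NULL, profiles = "static")
  tr <- simulate_prediction_experiment(des, pop)
  s <- tapply(tr$response_s, tr$occlusion_s, sd)
  expect_equal(unname(s[["1"]] / s[["0.5"]]), 2.0, tolerance = 0.1)
})

test_that("2IFC choices are unbiased at the percept mean and follow the bias", {
  pop0 <- noise_free_pop()
  obs0 <- make_observer(weber_speed = 0, weber_distance = 0)
  tr <- simulate_2ifc_trial(4, 10, "static", obs0, pop0)
  expect_true(tr$chose_cloud)
  # at the percept mean the choice is a fair coin
  obs <- make_observer(bias_opposite = 0.2, weber_speed = 0.1)
  pop <- population_spec()
  set.seed(13)
  n <- 10000
  ball <- perceived_speed_sample(4, "opposite", obs, 3.6, n = n)
  cloud <- 4.72 * (1 + 0.1 * rnorm(n))
  expect_equal(mean(cloud > ball), 0.5, tolerance = 0.02)
})

test_that("the choice psychometric function is centred at the biased percept", {
  # brute-force sweep: the 50% point sits at v + bias * nominal = 4.72
  set.seed(14)
  n <- 20000
  obs <- make_observer(bias_opposite = 0.2, weber_speed = 0.1)
  levels <- runif(n, 3.2, 6.4)
  ball <- perceived_speed_sample(4, "opposite", obs, 3.6, n = n)
  cloud <- levels * (1 + 0.1 * rnorm(n))
  fit <- fit_cumulative_gaussian(levels, cloud > ball)
  expect_equal(fit$pse, 4.72, tolerance = 0.05)
})

test_that("zero-effect populations leave the motion profiles indistinguishable", {
  set.seed(15)
  pop0 <- null_population_spec()
  des <- prediction_design(4, 100, extra_occlusions = NULL)
  tr <- simulate_prediction_experiment(des, pop0)
  cellmeans <- tapply(tr$error_s, tr$motion_profile, mean)
  sem <- tapply(tr$error_s, tr$motion_profile, function(x) sd(x) / sqrt(length(x)))
  expect_lt(abs(cellmeans[["opposite"]] - cellmeans[["static"]]),
            2 * sqrt(sem[["opposite"]]^2 + sem[["static"]]^2) * 2)
})

test_that("trial tables serialise to CSV and back", {
  set.seed(16)
  tr <- simulate_prediction_experiment(prediction_design(1, 1), population_spec())
  path <- tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$response_s, tr$response_s, tolerance = 1e-12)
  unlink(path)
})
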