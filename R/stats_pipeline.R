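#' Outlier filter for prediction-task trials
#'
#' Drops trials whose response time exceeds three times the occlusion duration
#' (strictly more than; a response at exactly three times is kept), taken to
#' indicate a missed trial. When head-rotation bin columns are present
#' (numeric columns named `head_bin_*`, degrees), trials where half or more of
#' the recorded bins lie outside +-2.5 degrees are dropped as well. Malformed
#' rows (missing response or occlusion) are collected into the dropped report.
#'
#' @param trials prediction-task trial table.
#' @return a list with `kept` (tibble) and `dropped` (tibble with a `reason`
#'   column accounting for every removed row).
#' @export
filter_prediction_trials <- function(trials) {
  need <- c("response_s", "occlusion_s")
  if (!all(need %in% names(trials))) {
    stop("`trials` must have `response_s` and `occlusion_s` columns", call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(trials))
  bad_row <- !is.finite(trials$response_s) | !is.finite(trials$occlusion_s)
  reason[bad_row] <- "malformed"
  late <- !bad_row & trials$response_s > 3 * trials$occlusion_s
  reason[late] <- "response > 3 x occlusion"
  head_cols <- grep("^head_bin", names(trials), value = TRUE)
  if (length(head_cols) > 0) {
    bins <- abs(as.matrix(trials[, head_cols, drop = FALSE]))
    frac_out <- rowMeans(bins > 2.5, na.rm = TRUE)
    head_bad <- is.na(reason) & frac_out >= 0.5
    reason[head_bad] <- "head rotation out of range"
  }
  keep <- is.na(reason)
  list(
    kept = trials[keep, , drop = FALSE],
    dropped = dplyr::mutate(trials[!keep, , drop = FALSE], reason = reason[!keep])
  )
}

#' Boundary filter for speed-estimation staircases
#'
#' Drops a whole staircase when more than 20% of its presented levels sit
#' exactly at a staircase bound (levels are clipped, so boundary contact is
#' exact up to floating-point tolerance). Bounds default to one third and
#' three times the single-ball speed and can be overridden by `lower_bound` /
#' `upper_bound` columns.
#'
#' @param trials speed-estimation trial table keyed by `staircase_id`.
#' @return list with `kept` and `dropped` trial tables; dropped rows carry the
#'   offending staircase's boundary fraction.
#' @export
filter_staircases <- function(trials) {
  need <- c("staircase_id", "ball_speed_mps", "cloud_speed_mps")
  if (!all(need %in% names(trials))) {
    stop("`trials` must follow the speed-estimation schema", call. = FALSE)
  }
  lo <- if ("lower_bound" %in% names(trials)) trials$lower_bound else trials$ball_speed_mps / 3
  hi <- if ("upper_bound" %in% names(trials)) trials$upper_bound else 3 * trials$ball_speed_mps
  tol <- 1e-9
  at_bound <- abs(trials$cloud_speed_mps - lo) < tol | abs(trials$cloud_speed_mps - hi) < tol
  frac <- stats::ave(as.numeric(at_bound), trials$staircase_id, FUN = mean)
  drop <- frac > 0.20
  list(
    kept = trials[!drop, , drop = FALSE],
    dropped = dplyr::mutate(trials[drop, , drop = FALSE], bound_fraction = frac[drop])
  )
}

#' Per-condition summaries of extrapolated time
#'
#' Mean and SD of the produced (extrapolated) interval per participant x ball
#' speed x motion profile x occlusion duration. Cells with an SD at or below
#' 0.01 s are flagged for exclusion from precision analyses (their log-SD
#' would be an extreme leverage point).
#'
#' @param trials filtered prediction-task trials.
#' @return tibble of condition summaries with `mean_extrapolated_s`,
#'   `sd_extrapolated_s`, `n_trials`, `precision_excluded`.
#' @export
prediction_condition_summaries <- function(trials) {
  trials |>
    dplyr::group_by(.data$participant_id, .data$ball_speed_mps,
                    .data$motion_profile, .data$occlusion_s) |>
    dplyr::summarise(
      mean_extrapolated_s = mean(.data$response_s),
      sd_extrapolated_s = stats::sd(.data$response_s),
      mean_error_s = mean(.data$error_s),
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(precision_excluded = !is.finite(.data$sd_extrapolated_s) |
                    .data$sd_extrapolated_s <= 0.01)
}

# ---- mixed-model machinery ----------------------------------------------

profile_factor <- function(x) factor(x, levels = c("static", "same", "opposite"))

lmer_quiet <- function(formula, data) {
  withCallingHandlers(
    suppressMessages(
      lme4::lmer(formula, data = data, REML = FALSE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore",
                   optCtrl = list(xtol_abs = 1e-6, ftol_abs = 1e-6)
                 ))
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

# fit, falling back to a diagonal random-effect covariance on singularity
fit_lmm_with_fallback <- function(formula_full, formula_diag, data) {
  fit <- lmer_quiet(formula_full, data)
  tag <- deparse1(formula_full)
  refit <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    fit2 <- lmer_quiet(formula_diag, data)
    if (!lme4::isSingular(fit2, tol = 1e-4)) {
      fit <- fit2
      tag <- paste(deparse1(formula_diag), "(diagonal fallback)")
      refit <- TRUE
    }
  }
  list(fit = fit, formula_tag = tag, refit_diagonal = refit,
       singular = lme4::isSingular(fit, tol = 1e-4))
}

wald_coefficients <- function(fit) {
  cc <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(cc),
    estimate = unname(cc[, "Estimate"]),
    se = unname(cc[, "Std. Error"]),
    z = unname(cc[, "t value"]),
    p_wald = unname(2 * stats::pnorm(-abs(cc[, "t value"])))
  )
}

new_lmm_result <- function(fitted, coefs, n_obs) {
  structure(
    list(formula_tag = fitted$formula_tag,
         coefficients = coefs,
         log_lik = as.numeric(stats::logLik(fitted$fit)),
         singular = fitted$singular,
         refit_diagonal = fitted$refit_diagonal,
         n_obs = n_obs,
         fit = fitted$fit),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result>", x$formula_tag, "\n")
  cat(sprintf("  logLik %.2f on %d observations%s\n", x$log_lik, x$n_obs,
              if (x$singular) " (singular fit)" else ""))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Accuracy model for the prediction task
#'
#' Linear mixed model of the signed timing error on the motion profile
#' (static observer as reference), with a random ball-speed slope per
#' participant and a random intercept per occlusion duration:
#' `error ~ profile + (speed | participant) + (1 | occlusion)`. Fitted by
#' maximum likelihood. A singular random-effect covariance triggers a
#' flagged refit with a diagonal covariance. Under the generative model an
#' opposite-direction bias makes the opposite coefficient negative (earlier
#' button presses).
#'
#' @param trials filtered prediction-task trials.
#' @param occlusions optional occlusion durations to restrict the fit to
#'   (e.g. `c(0.5, 0.6, 0.7)` for the main design); `NULL` uses all rows.
#' @param n_boot number of parametric-bootstrap replicates for 95% CIs on the
#'   fixed effects; 0 skips the bootstrap (Wald p-values are always reported).
#' @param seed RNG seed for the bootstrap.
#' @return an `lmm_result` with a tidy coefficient table.
#' @export
accuracy_lmm_prediction <- function(trials, occlusions = NULL, n_boot = 0,
                                    seed = NULL) {
  d <- trials
  if (!is.null(occlusions)) d <- d[d$occlusion_s %in% occlusions, , drop = FALSE]
  if (nrow(d) == 0) stop("no trials to fit", call. = FALSE)
  d$motion_profile <- profile_factor(d$motion_profile)
  d$occlusion_f <- factor(d$occlusion_s)
  fitted <- fit_lmm_with_fallback(
    error_s ~ motion_profile + (ball_speed_mps | participant_id) + (1 | occlusion_f),
    error_s ~ motion_profile + (ball_speed_mps || participant_id) + (1 | occlusion_f),
    d
  )
  coefs <- wald_coefficients(fitted$fit)
  if (n_boot > 0) {
    ci <- bootstrap_ci(fitted$fit, n_boot = n_boot, seed = seed)
    coefs <- dplyr::left_join(coefs, ci, by = "term")
  }
  new_lmm_result(fitted, coefs, nrow(d))
}

new_lrt_result <- function(ll_test, ll_null, df, extra = list()) {
  stat <- max(0, 2 * (ll_test - ll_null))
  structure(
    c(list(statistic = stat, df = df,
           p_value = stats::pchisq(stat, df, lower.tail = FALSE),
           log_lik_test = ll_test, log_lik_null = ll_null),
      extra),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> chisq=%.3f df=%d p=%.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Precision comparison for the prediction task
#'
#' Likelihood-ratio test of the motion-profile term on log condition SDs of
#' the extrapolated time, controlling for the mean extrapolated time (biases
#' shorten the produced interval and thereby shrink its SD). Run separately
#' for one self-motion profile against static. Coefficients are not reported
#' as effects: the mean is a confounded covariate.
#'
#' @param summaries output of [prediction_condition_summaries()].
#' @param profile `"opposite"` or `"same"` (tested against `"static"`).
#' @return an `lrt_result`; also carries the test model's profile coefficient
#'   sign for direction checks.
#' @export
precision_lrt_prediction <- function(summaries, profile = c("opposite", "same")) {
  profile <- match.arg(profile)
  d <- summaries[!summaries$precision_excluded &
                   summaries$motion_profile %in% c("static", profile), , drop = FALSE]
  if (nrow(d) == 0) stop("no usable condition summaries", call. = FALSE)
  d$motion_profile <- droplevels(profile_factor(d$motion_profile))
  d$occlusion_f <- factor(d$occlusion_s)
  d$log_sd <- log(d$sd_extrapolated_s)
  test <- fit_lmm_with_fallback(
    log_sd ~ mean_extrapolated_s + motion_profile +
      (ball_speed_mps | participant_id) + (1 | occlusion_f),
    log_sd ~ mean_extrapolated_s + motion_profile +
      (ball_speed_mps || participant_id) + (1 | occlusion_f),
    d
  )
  null <- fit_lmm_with_fallback(
    log_sd ~ mean_extrapolated_s + (ball_speed_mps | participant_id) + (1 | occlusion_f),
    log_sd ~ mean_extrapolated_s + (ball_speed_mps || participant_id) + (1 | occlusion_f),
    d
  )
  co <- lme4::fixef(test$fit)
  term <- grep("motion_profile", names(co), value = TRUE)[1]
  new_lrt_result(as.numeric(stats::logLik(test$fit)),
                 as.numeric(stats::logLik(null$fit)), df = 1,
                 extra = list(profile = profile,
                              profile_coefficient = unname(co[term])))
}

#' Accuracy model for the speed-estimation task
#'
#' Linear mixed model of the fitted PSEs on the motion profile with a random
#' ball-speed slope per participant: `PSE ~ profile + (speed | participant)`.
#' Only converged psychometric fits enter. A positive opposite-direction
#' coefficient indicates speed overestimation under opposing self-motion.
#'
#' @param fits psychometric fit table from [fit_psychometric_all()].
#' @inheritParams accuracy_lmm_prediction
#' @return an `lmm_result`.
#' @export
pse_lmm <- function(fits, n_boot = 0, seed = NULL) {
  d <- fits[fits$converged & is.finite(fits$pse_mps), , drop = FALSE]
  if (nrow(d) == 0) stop("no converged fits", call. = FALSE)
  d$motion_profile <- profile_factor(d$motion_profile)
  fitted <- fit_lmm_with_fallback(
    pse_mps ~ motion_profile + (ball_speed_mps | participant_id),
    pse_mps ~ motion_profile + (ball_speed_mps || participant_id),
    d
  )
  coefs <- wald_coefficients(fitted$fit)
  if (n_boot > 0) {
    ci <- bootstrap_ci(fitted$fit, n_boot = n_boot, seed = seed)
    coefs <- dplyr::left_join(coefs, ci, by = "term")
  }
  new_lmm_result(fitted, coefs, nrow(d))
}

#' Precision comparison for the speed-estimation task
#'
#' Likelihood-ratio test of the motion-profile term on log JNDs, controlling
#' for the PSE, separately per self-motion profile against static:
#' `log(JND) ~ profile + PSE + (speed | participant)` versus the model without
#' the profile term.
#'
#' @inheritParams pse_lmm
#' @param profile `"opposite"` or `"same"`.
#' @return an `lrt_result`.
#' @export
jnd_lrt <- function(fits, profile = c("opposite", "same")) {
  profile <- match.arg(profile)
  d <- fits[fits$converged & is.finite(fits$jnd_mps) & fits$jnd_mps > 0 &
              fits$motion_profile %in% c("static", profile), , drop = FALSE]
  if (nrow(d) == 0) stop("no converged fits", call. = FALSE)
  d$motion_profile <- droplevels(profile_factor(d$motion_profile))
  d$log_jnd <- log(d$jnd_mps)
  test <- fit_lmm_with_fallback(
    log_jnd ~ motion_profile + pse_mps + (ball_speed_mps | participant_id),
    log_jnd ~ motion_profile + pse_mps + (ball_speed_mps || participant_id),
    d
  )
  null <- fit_lmm_with_fallback(
    log_jnd ~ pse_mps + (ball_speed_mps | participant_id),
    log_jnd ~ pse_mps + (ball_speed_mps || participant_id),
    d
  )
  co <- lme4::fixef(test$fit)
  term <- grep("motion_profile", names(co), value = TRUE)[1]
  new_lrt_result(as.numeric(stats::logLik(test$fit)),
                 as.numeric(stats::logLik(null$fit)), df = 1,
                 extra = list(profile = profile,
                              profile_coefficient = unname(co[term])))
}

# per-participant cross-task differences (profile minus static)
cross_task_differences <- function(summaries, fits, profile,
                                   occlusions = c(0.5, 0.6, 0.7)) {
  pred <- summaries[summaries$occlusion_s %in% occlusions &
                      summaries$motion_profile %in% c("static", profile), ,
                    drop = FALSE]
  pred_diff <- pred |>
    dplyr::group_by(.data$participant_id, .data$motion_profile) |>
    dplyr::summarise(mean_t = mean(.data$mean_extrapolated_s),
                     sd_t = mean(.data$sd_extrapolated_s, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "motion_profile",
                       values_from = c("mean_t", "sd_t")) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      mean_diff_s = .data[[paste0("mean_t_", profile)]] - .data$mean_t_static,
      sd_diff_s = .data[[paste0("sd_t_", profile)]] - .data$sd_t_static
    )
  se <- fits[fits$converged & fits$motion_profile %in% c("static", profile), ,
             drop = FALSE] |>
    dplyr::group_by(.data$participant_id, .data$motion_profile) |>
    dplyr::summarise(pse = mean(.data$pse_mps), jnd = mean(.data$jnd_mps),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "motion_profile",
                       values_from = c("pse", "jnd")) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      pse_diff_mps = .data[[paste0("pse_", profile)]] - .data$pse_static,
      jnd_diff_mps = .data[[paste0("jnd_", profile)]] - .data$jnd_static
    )
  dplyr::inner_join(pred_diff, se, by = "participant_id") |>
    dplyr::filter(is.finite(.data$mean_diff_s), is.finite(.data$pse_diff_mps))
}

#' Cross-task accuracy relation
#'
#' Regresses each participant's self-motion effect on mean extrapolated time
#' (profile minus static, prediction task) on their PSE shift (speed
#' estimation task). Under shared generative biases the slope is negative:
#' a larger speed overestimation goes with earlier button presses.
#'
#' @param summaries prediction condition summaries.
#' @param fits psychometric fit table.
#' @param profile self-motion profile compared against static.
#' @return list with the fitted `lm`, `slope`, `ci` (95%), `p_value`, `n`.
#' @export
bias_correlation <- function(summaries, fits, profile = c("opposite", "same")) {
  profile <- match.arg(profile)
  d <- cross_task_differences(summaries, fits, profile)
  if (nrow(d) < 5) stop("need at least 5 participants", call. = FALSE)
  if (stats::sd(d$pse_diff_mps) < 1e-12) {
    stop("degenerate regressor: PSE differences are constant", call. = FALSE)
  }
  fit <- stats::lm(mean_diff_s ~ pse_diff_mps, data = d)
  ci <- stats::confint(fit)["pse_diff_mps", ]
  list(fit = fit,
       slope = unname(stats::coef(fit)["pse_diff_mps"]),
       ci = unname(ci),
       p_value = summary(fit)$coefficients["pse_diff_mps", "Pr(>|t|)"],
       n = nrow(d))
}

#' Cross-task precision relation
#'
#' Likelihood-ratio test of whether each participant's JND shift (speed
#' estimation) explains their SD shift in extrapolated time (prediction task)
#' beyond what the mean shift already accounts for:
#' `sd_diff ~ mean_diff + jnd_diff` versus `sd_diff ~ mean_diff`.
#'
#' @inheritParams bias_correlation
#' @return an `lrt_result` with the JND-difference coefficient attached.
#' @export
precision_link_lrt <- function(summaries, fits, profile = c("opposite", "same")) {
  profile <- match.arg(profile)
  d <- cross_task_differences(summaries, fits, profile)
  d <- d[is.finite(d$sd_diff_s) & is.finite(d$jnd_diff_mps), , drop = FALSE]
  if (nrow(d) < 5) stop("need at least 5 participants", call. = FALSE)
  if (stats::sd(d$jnd_diff_mps) < 1e-12 || stats::sd(d$mean_diff_s) < 1e-12) {
    stop("degenerate regressor in precision-link model", call. = FALSE)
  }
  test <- stats::lm(sd_diff_s ~ mean_diff_s + jnd_diff_mps, data = d)
  null <- stats::lm(sd_diff_s ~ mean_diff_s, data = d)
  new_lrt_result(as.numeric(stats::logLik(test)), as.numeric(stats::logLik(null)),
                 df = 1,
                 extra = list(profile = profile,
                              jnd_coefficient = unname(stats::coef(test)["jnd_diff_mps"]),
                              n = nrow(d)))
}

#' Parametric-bootstrap confidence intervals for fixed effects
#'
#' Simulates response vectors from the fitted model, refits, and returns
#' percentile 95% intervals for every fixed effect. Deterministic under a
#' fixed seed. Works for `lm` and `lme4` fits. If more than 10% of bootstrap
#' refits fail, the intervals from the successful refits are returned with a
#' warning.
#'
#' @param fit an `lm` or `merMod` object.
#' @param n_boot number of bootstrap replicates (at least 200).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return tibble with `term`, `ci_low`, `ci_high`, `n_boot_ok`.
#' @export
bootstrap_ci <- function(fit, n_boot = 500, seed = NULL, level = 0.95) {
  if (n_boot < 200) stop("`n_boot` must be at least 200", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - level) / 2
  if (inherits(fit, "merMod")) {
    bb <- suppressMessages(suppressWarnings(
      lme4::bootMer(fit, lme4::fixef, nsim = n_boot, type = "parametric")
    ))
    draws <- bb$t
  } else {
    sims <- stats::simulate(fit, nsim = n_boot)
    mf <- stats::model.frame(fit)
    cf <- stats::coef(fit)
    raw <- vapply(seq_len(n_boot), function(i) {
      mf[[1]] <- sims[[i]]
      tryCatch(stats::coef(stats::lm(stats::formula(fit), data = mf)),
               error = function(e) rep(NA_real_, length(cf)))
    }, numeric(length(cf)))
    draws <- if (length(cf) == 1) matrix(raw, ncol = 1) else t(raw)
    colnames(draws) <- names(cf)
  }
  ok <- stats::complete.cases(draws)
  if (mean(ok) < 0.9) {
    warning(sprintf("%.0f%% of bootstrap refits failed; intervals use the rest",
                    100 * (1 - mean(ok))))
  }
  draws <- draws[ok, , drop = FALSE]
  tibble::tibble(
    term = colnames(draws),
    ci_low = unname(apply(draws, 2, stats::quantile, probs = alpha, na.rm = TRUE)),
    ci_high = unname(apply(draws, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)),
    n_boot_ok = sum(ok)
  )
}

#' Tidy coefficient export
#'
#' Serialises an `lmm_result` coefficient table (plus optional test results)
#' to the package's tidy CSV layout.
#'
#' @param x an `lmm_result`.
#' @param path output CSV path.
#' @export
write_coefficients_csv <- function(x, path) {
  stopifnot(inherits(x, "lmm_result"))
  utils::write.csv(as.data.frame(x$coefficients), path, row.names = FALSE)
  invisible(path)
}
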