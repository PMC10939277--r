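#' Fit a cumulative-Gaussian psychometric function by maximum likelihood
#'
#' Two-parameter fit of `P(choose comparison | level x) = pnorm((x - pse) / jnd)`
#' to binary choices by direct maximisation of the Bernoulli likelihood
#' (no lapse or guess parameters). The mean of the fitted Gaussian is the
#' point of subjective equality (PSE); its standard deviation is the 84.1%
#' just-noticeable difference (JND).
#'
#' Optimisation uses bounded quasi-Newton (`L-BFGS-B`) with an analytic
#' gradient from four deterministic starts (PSE at the level mean plus/minus
#' one level SD, JND at 0.5 and 1.5 times the level SD); the best likelihood
#' wins, ties broken by the first start. The JND is constrained to
#' `[1e-3, 3 * level range]`. Degenerate data (a single level, one response
#' category, or complete separation driving the JND to its lower constraint)
#' yield `converged = FALSE` with a diagnostic rather than an error.
#'
#' @param levels numeric vector of comparison levels (m/s).
#' @param chose_comparison logical vector, `TRUE` when the comparison was
#'   judged faster.
#' @param starts optional list of `c(pse, jnd)` start points overriding the
#'   four deterministic defaults (used by simulation loops where a single
#'   data-driven start is sufficient).
#' @return a list of class `psychometric_fit`: `pse`, `jnd`, `nll`,
#'   `n_trials`, `converged`, `message`.
#' @export
fit_cumulative_gaussian <- function(levels, chose_comparison, starts = NULL) {
  if (length(levels) != length(chose_comparison)) {
    stop("`levels` and `chose_comparison` must have equal length", call. = FALSE)
  }
  keep <- is.finite(levels) & !is.na(chose_comparison)
  x <- as.numeric(levels[keep])
  y <- as.numeric(chose_comparison[keep])
  n <- length(x)
  if (n < 10) stop("need at least 10 trials to fit", call. = FALSE)

  rng <- diff(range(x))
  result <- function(pse, jnd, nll, converged, msg) {
    structure(list(pse = pse, jnd = jnd, nll = nll, n_trials = n,
                   converged = converged, message = msg),
              class = "psychometric_fit")
  }
  if (rng == 0) {
    return(result(x[1], NA_real_, NA_real_, FALSE, "single level"))
  }
  if (all(y == 1) || all(y == 0)) {
    return(result(NA_real_, NA_real_, NA_real_, FALSE, "one response category"))
  }

  # squeeze probabilities into (eps, 1 - eps) smoothly; shared z/p cache since
  # optim evaluates fn and gr back-to-back at the same parameters
  eps <- 1e-12
  squeeze <- 1 - 2 * eps
  ny <- 1 - y
  cache <- new.env(parent = emptyenv())
  cache$par <- c(NA_real_, NA_real_)
  eval_pz <- function(par) {
    if (identical(par, cache$par)) return(cache$val)
    z <- (x - par[1]) / par[2]
    p <- eps + squeeze * stats::pnorm(z)
    cache$par <- par
    cache$val <- list(z = z, p = p)
    cache$val
  }
  nll_fun <- function(par) {
    v <- eval_pz(par)
    -sum(y * log(v$p) + ny * log1p(-v$p))
  }
  grad_fun <- function(par) {
    v <- eval_pz(par)
    w <- (v$p - y) / (v$p * (1 - v$p)) * stats::dnorm(v$z)
    -c(sum(w), sum(w * v$z)) / par[2]
  }

  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- rng / 4
  jnd_lo <- 1e-3
  jnd_hi <- 3 * rng
  if (is.null(starts)) {
    starts <- list(
      c(m - s, 0.5 * s), c(m - s, 1.5 * s),
      c(m + s, 0.5 * s), c(m + s, 1.5 * s)
    )
  }
  lower <- c(min(x) - 3 * rng, jnd_lo)
  upper <- c(max(x) + 3 * rng, jnd_hi)
  best <- NULL
  for (st in starts) {
    st[2] <- min(max(st[2], jnd_lo), jnd_hi)
    fit <- tryCatch(
      stats::optim(st, nll_fun, grad_fun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e8)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) {
    return(result(NA_real_, NA_real_, NA_real_, FALSE, "optimisation failed"))
  }
  pse <- best$par[1]
  jnd <- best$par[2]
  at_jnd_floor <- jnd <= jnd_lo * (1 + 1e-6)
  at_pse_bound <- pse <= lower[1] + 1e-8 || pse >= upper[1] - 1e-8
  msg <- if (at_jnd_floor) {
    "jnd at lower constraint (separation?)"
  } else if (at_pse_bound) {
    "pse at search bound"
  } else if (best$convergence != 0) {
    paste("optim convergence code", best$convergence)
  } else {
    "ok"
  }
  result(pse, jnd, best$value,
         msg == "ok", msg)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> pse=%.3f jnd=%.3f nll=%.2f n=%d %s\n",
              x$pse, x$jnd, x$nll, x$n_trials,
              if (x$converged) "" else paste0("[", x$message, "]")))
  invisible(x)
}

#' Fit psychometric functions for every condition cell
#'
#' Pools the two staircases of each participant x ball speed x motion profile
#' cell and fits one cumulative Gaussian per cell. Cells whose fit fails are
#' reported with `converged = FALSE`, not dropped silently.
#'
#' @param trials speed-estimation trial table (columns `participant_id`,
#'   `ball_speed_mps`, `motion_profile`, `cloud_speed_mps`, `chose_cloud`).
#' @return tibble with one row per cell: `participant_id`, `ball_speed_mps`,
#'   `motion_profile`, `pse_mps`, `jnd_mps`, `nll`, `n_trials`, `converged`,
#'   `message`.
#' @export
fit_psychometric_all <- function(trials) {
  need <- c("participant_id", "ball_speed_mps", "motion_profile",
            "cloud_speed_mps", "chose_cloud")
  if (!all(need %in% names(trials))) {
    stop("`trials` must follow the speed-estimation schema", call. = FALSE)
  }
  key <- paste(trials$participant_id, trials$ball_speed_mps, trials$motion_profile,
               sep = "\r")
  groups <- split(seq_len(nrow(trials)), key)
  rows <- lapply(groups, function(idx) {
    f <- tryCatch(
      fit_cumulative_gaussian(trials$cloud_speed_mps[idx], trials$chose_cloud[idx]),
      error = function(e) list(pse = NA_real_, jnd = NA_real_, nll = NA_real_,
                               n_trials = length(idx), converged = FALSE,
                               message = paste("fit error:", conditionMessage(e)))
    )
    list(participant_id = trials$participant_id[idx[1]],
         ball_speed_mps = trials$ball_speed_mps[idx[1]],
         motion_profile = trials$motion_profile[idx[1]],
         pse_mps = f$pse, jnd_mps = f$jnd, nll = f$nll,
         n_trials = f$n_trials, converged = f$converged, message = f$message)
  })
  rows <- unname(rows)
  out <- tibble::tibble(
    participant_id = vapply(rows, `[[`, numeric(1), "participant_id"),
    ball_speed_mps = vapply(rows, `[[`, numeric(1), "ball_speed_mps"),
    motion_profile = vapply(rows, `[[`, character(1), "motion_profile"),
    pse_mps = vapply(rows, `[[`, numeric(1), "pse_mps"),
    jnd_mps = vapply(rows, `[[`, numeric(1), "jnd_mps"),
    nll = vapply(rows, `[[`, numeric(1), "nll"),
    n_trials = vapply(rows, function(r) as.numeric(r$n_trials), numeric(1)),
    converged = vapply(rows, `[[`, logical(1), "converged"),
    message = vapply(rows, `[[`, character(1), "message")
  )
  dplyr::arrange(out, .data$participant_id, .data$ball_speed_mps, .data$motion_profile)
}
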