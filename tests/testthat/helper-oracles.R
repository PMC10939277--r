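# shared test helpers: noise-free populations, hand-built observers and a
# brute-force likelihood oracle for the psychometric fit

noise_free_pop <- function(bias_mean = 0.20, ...) {
  population_spec(bias_mean = bias_mean, bias_sd = 0,
                  precision_effect_mean = 0, precision_effect_sd = 0,
                  weber_speed_mean = 0, weber_speed_sd = 0,
                  weber_distance = 0, ...)
}

make_observer <- function(id = 1L, bias_opposite = 0.2, bias_same = 0,
                          precision_opposite = 0, precision_same = 0,
                          weber_speed = 0.1, weber_distance = 0.05) {
  tibble::tibble(
    participant_id = id, bias_opposite = bias_opposite, bias_same = bias_same,
    precision_opposite = precision_opposite, precision_same = precision_same,
    weber_speed = weber_speed, weber_distance = weber_distance
  )
}

# exhaustive grid search over (pse, jnd) of the Bernoulli likelihood
grid_search_cg <- function(x, y, n_grid = 200) {
  ps <- seq(min(x), max(x), length.out = n_grid)
  js <- seq(0.01, diff(range(x)), length.out = n_grid)
  best <- c(pse = NA, jnd = NA, nll = Inf)
  for (p in ps) {
    pr <- outer(x, js, function(xx, j) stats::pnorm((xx - p) / j))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    nll <- -colSums(y * log(pr) + (1 - y) * log(1 - pr))
    i <- which.min(nll)
    if (nll[i] < best[3]) best <- c(p, js[i], nll[i])
  }
  best
}

# responder factories for staircase tests
alternating_responder <- function() {
  i <- 0L
  function(level) {
    i <<- i + 1L
    i %% 2L == 0L
  }
}

constant_responder <- function(value = TRUE) function(level) value

scripted_responder <- function(responses) {
  i <- 0L
  function(level) {
    i <<- i + 1L
    responses[i]
  }
}
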