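# Independent oracles used across the suite.  Each is a deliberately naive,
# literal implementation kept separate from the package's code paths.

# Literal transcription of the two-dimensional spiking-bursting map.
oracle_rulkov <- function(alpha, sigma, mu, x0, xp0, y0, n, input = 0) {
  x <- x0; xp <- xp0; y <- y0
  out <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    ye <- y + input
    xn <- if (x <= 0) {
      alpha / (1 - x) + ye
    } else if (x < alpha + ye && xp <= 0) {
      alpha + ye
    } else {
      -1
    }
    yn <- y - mu * (x + 1) + mu * sigma
    xp <- x; x <- xn; y <- yn
    out[k, ] <- c(x, y)
  }
  out
}

# Closed-form fixed point of the slow graded gate at constant activation.
oracle_graded_fixed_point <- function(k1, k2, a) k1 * a / (k1 * a + k2)

# Brute-force latency statistics.
oracle_latency_stats <- function(lat, thr) {
  list(min = min(lat), max = max(lat), mean = mean(lat), sd = stats::sd(lat),
       jitter = max(lat) - min(lat), failures = sum(lat > thr))
}

# Empirical convergence order by Richardson slope fit on y' = -y, y(0) = 1,
# integrated to t = 1.
oracle_convergence_order <- function(method, dts = 0.1 / 2^(0:3)) {
  errs <- vapply(dts, function(dt) {
    spec <- integrator_spec(method, dt = dt)
    y <- 1; t <- 0
    n <- round(1 / dt)
    for (i in seq_len(n)) {
      y <- integrate_step(spec, function(t, y) -y, y, t, dt)$y
      t <- t + dt
    }
    abs(y - exp(-1))
  }, numeric(1))
  fit <- stats::lm(log(errs) ~ log(dts))
  unname(stats::coef(fit)[2])
}

# Mean steady-state burst duration: boundary-truncated first/last events are
# excluded.
steady_burst_duration <- function(bursts) {
  if (nrow(bursts) > 4) bursts <- bursts[2:(nrow(bursts) - 1), ]
  mean(bursts$duration)
}

stock_models <- c("rulkov_bursting", "izhikevich_bursting",
                  "hindmarsh_rose_bursting", "ghigliazza_holmes_bursting",
                  "wang_bursting")
validation_models <- setdiff(stock_models, "wang_bursting")
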