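#' Numerical integrators for the ODE neuron models
#'
#' Fixed-step schemes (forward Euler, Heun, classic fourth-order Runge-Kutta)
#' plus a six-stage embedded Runge-Kutta pair (`"rk65"`) that advances with
#' the fifth-order solution and returns the embedded fourth-order error
#' estimate for step control.
#'
#' @param method One of `"euler"`, `"heun"`, `"rk4"`, `"rk65"`.
#' @param dt Default step in model-time units.
#' @param atol,rtol Absolute/relative tolerances for adaptive `"rk65"`
#'   integration.
#' @param dt_min,dt_max Step bounds for the adaptive driver.
#' @return An `integrator_spec` object.
#' @export
integrator_spec <- function(method = c("rk4", "euler", "heun", "rk65"),
                            dt = 0.01, atol = 1e-8, rtol = 1e-8,
                            dt_min = 1e-10, dt_max = Inf) {
  method <- match.arg(method)
  assert_scalar_pos(dt)
  structure(list(method = method, dt = dt, atol = atol, rtol = rtol,
                 dt_min = dt_min, dt_max = dt_max),
            class = "integrator_spec")
}

# Six-stage Fehlberg embedded pair: propagate order 5, embedded order 4.
.rkf_c <- c(0, 1 / 4, 3 / 8, 12 / 13, 1, 1 / 2)
.rkf_a <- list(
  c(1 / 4),
  c(3 / 32, 9 / 32),
  c(1932 / 2197, -7200 / 2197, 7296 / 2197),
  c(439 / 216, -8, 3680 / 513, -845 / 4104),
  c(-8 / 27, 2, -3544 / 2565, 1859 / 4104, -11 / 40))
.rkf_b5 <- c(16 / 135, 0, 6656 / 12825, 28561 / 56430, -9 / 50, 2 / 55)
.rkf_b4 <- c(25 / 216, 0, 1408 / 2565, 2197 / 4104, -1 / 5, 0)

#' Advance one integration step
#'
#' @param spec An [integrator_spec()].
#' @param f Derivative function `f(t, y)` returning `dy/dt`; must be pure.
#' @param y Current state vector.
#' @param t Current time.
#' @param dt Step size (defaults to `spec$dt`).
#' @return A list with `y` (the new state) and, for `"rk65"`, `err` (the
#'   embedded error estimate vector); fixed-step methods return `err = NULL`.
#' @export
integrate_step <- function(spec, f, y, t, dt = spec$dt) {
  assert_scalar_pos(dt)
  k1 <- f(t, y)
  if (!all(is.finite(k1))) {
    stop_bad(sprintf("non-finite derivative at t = %g (state: %s)", t,
                     paste(signif(y, 4), collapse = ", ")),
             class = "hybridclamp_nonfinite")
  }
  switch(spec$method,
    euler = list(y = y + dt * k1, err = NULL),
    heun = {
      yp <- y + dt * k1
      k2 <- f(t + dt, yp)
      list(y = y + dt * 0.5 * (k1 + k2), err = NULL)
    },
    rk4 = {
      k2 <- f(t + dt / 2, y + dt / 2 * k1)
      k3 <- f(t + dt / 2, y + dt / 2 * k2)
      k4 <- f(t + dt, y + dt * k3)
      list(y = y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), err = NULL)
    },
    rk65 = {
      ks <- list(k1)
      for (i in 2:6) {
        a <- .rkf_a[[i - 1]]
        incr <- a[1] * ks[[1]]
        if (i > 2) for (j in 2:(i - 1)) incr <- incr + a[j] * ks[[j]]
        ks[[i]] <- f(t + .rkf_c[i] * dt, y + dt * incr)
      }
      y5 <- y; y4 <- y
      for (i in 1:6) {
        y5 <- y5 + dt * .rkf_b5[i] * ks[[i]]
        y4 <- y4 + dt * .rkf_b4[i] * ks[[i]]
      }
      list(y = y5, err = y5 - y4)
    })
}

#' Integrate over an interval with error control
#'
#' Fixed-step methods take `ceiling((t1 - t0)/spec$dt)` equal steps.  The
#' embedded pair adapts its step so every accepted step satisfies
#' `max(|err| / (atol + rtol * |y|)) <= 1`, with the classic 0.9 safety
#' factor and step-change limits.
#'
#' @inheritParams integrate_step
#' @param t0,t1 Integration interval.
#' @return A list with the final `y`, final `t`, and `n_steps` taken.
#' @export
integrate_adaptive <- function(spec, f, y, t0, t1) {
  if (t1 <= t0) stop_bad("`t1` must be > `t0`")
  if (spec$method != "rk65") {
    n <- max(1L, ceiling((t1 - t0) / spec$dt))
    h <- (t1 - t0) / n
    t <- t0
    for (i in seq_len(n)) {
      y <- integrate_step(spec, f, y, t, h)$y
      t <- t0 + i * h
    }
    return(list(y = y, t = t, n_steps = n))
  }
  t <- t0
  h <- min(spec$dt, t1 - t0)
  n_steps <- 0L
  while (t < t1 - 1e-14 * (t1 - t0)) {
    h <- min(h, t1 - t)
    st <- integrate_step(spec, f, y, t, h)
    scale <- spec$atol + spec$rtol * pmax(abs(y), abs(st$y))
    enorm <- max(abs(st$err) / scale)
    if (enorm <= 1 || h <= spec$dt_min) {
      y <- st$y
      t <- t + h
      n_steps <- n_steps + 1L
    }
    fac <- if (enorm > 0) 0.9 * enorm^(-1 / 5) else 5
    h <- min(max(h * min(max(fac, 0.2), 5), spec$dt_min), spec$dt_max)
  }
  list(y = y, t = t, n_steps = n_steps)
}

# Advance an ODE neuron model by `span` model-time in `n_sub` fixed substeps,
# applying discrete reset events after each substep.  Hot-loop helper shared
# by calibration, the virtual preparation and the experiment engine.
step_model <- function(model, state, span, n_sub, method = "rk4", input = 0,
                       t = 0) {
  f <- model$derivs
  ev <- model$events
  h <- span / n_sub
  for (i in seq_len(n_sub)) {
    k1 <- f(state, t, input)
    if (method == "euler") {
      state <- state + h * k1
    } else if (method == "heun") {
      k2 <- f(state + h * k1, t + h, input)
      state <- state + h * 0.5 * (k1 + k2)
    } else {
      k2 <- f(state + h / 2 * k1, t + h / 2, input)
      k3 <- f(state + h / 2 * k2, t + h / 2, input)
      k4 <- f(state + h * k3, t + h, input)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (!is.null(ev)) state <- ev(state)$state
    t <- t + h
  }
  state
}

#' Select the integration substep for a real-time interval
#'
#' Each loop interval must advance the model by a fixed amount of model time
#' (the interval budget).  `select_step()` finds the smallest number of
#' substeps whose step size survives a stability probe: one burst-length
#' simulation without non-finite values, state blow-up (|state| > 1e6) or
#' gating variables escaping `[0, 1]` (to 1e-9 slack).  The search is
#' deterministic: n = 1..8, then doubling up to `cap`.
#'
#' @param spec An [integrator_spec()]; its fixed-step method is probed.
#' @param model An ODE `neuron_model`.
#' @param interval_budget Model time to advance per interval (> 0).
#' @param probe_time Model-time length of the stability probe (defaults to
#'   roughly one burst of the shipped presets, `model$probe_time / 6`).
#' @param cap Largest substep count tried.
#' @return List with `n_substeps` and `dt_sub = interval_budget/n_substeps`.
#' @export
select_step <- function(spec, model, interval_budget, probe_time = NULL,
                        cap = 64L) {
  assert_scalar_pos(interval_budget)
  if (model$kind != "ode") stop_bad("step selection applies to ODE models")
  if (is.null(probe_time)) {
    probe_time <- if (is.finite(model$probe_time)) model$probe_time / 6 else
      1000 * interval_budget
  }
  candidates <- unique(c(1:8, 2^(4:12)))
  candidates <- candidates[candidates <= cap]
  n_int <- max(1L, ceiling(probe_time / interval_budget))
  for (n in candidates) {
    if (probe_stable(model, state = model$state0, span = interval_budget,
                     n_sub = n, n_int = n_int, method = spec$method)) {
      return(list(n_substeps = as.integer(n),
                  dt_sub = interval_budget / n))
    }
  }
  stop_bad(sprintf(
    "no stable substep found for model '%s' up to %d substeps (budget %g)",
    model$name, cap, interval_budget), class = "hybridclamp_unstable")
}

probe_stable <- function(model, state, span, n_sub, n_int, method) {
  g <- model$gating_idx
  ok <- tryCatch({
    for (k in seq_len(n_int)) {
      state <- step_model(model, state, span, n_sub, method)
      if (!all(is.finite(state)) || max(abs(state)) > 1e6) return(FALSE)
      if (length(g) &&
          (min(state[g]) < -1e-9 || max(state[g]) > 1 + 1e-9)) return(FALSE)
    }
    TRUE
  }, error = function(e) FALSE)
  ok
}
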