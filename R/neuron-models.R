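#' Neuron model library
#'
#' Constructors for the spiking-bursting neuron models used to build hybrid
#' circuits: a discrete two-dimensional map (Rulkov) and several
#' ordinary-differential-equation models (Izhikevich, Hindmarsh-Rose, and two
#' minimal conductance-based bursters).  A model object bundles its parameter
#' set, initial state, the designated membrane-voltage variable, its dynamics
#' (one map step or a pure derivative function), and any discrete reset rule.
#'
#' Model "voltage" is dimensionless for the map and Hindmarsh-Rose models (the
#' fast variable `x`) and in mV for Izhikevich and the conductance models; the
#' calibration layer owns all mapping onto a living neuron's mV range.
#'
#' @param alpha,sigma,mu Rulkov map nonlinearity gain, bias and slow rate
#'   (dimensionless, `mu` small and positive).
#' @param x0,y0 Initial fast/slow state of the map.
#' @name neuron_models
NULL

new_neuron_model <- function(name, kind, params, state0, v_var,
                             map_step = NULL, derivs = NULL, events = NULL,
                             gating_idx = integer(), native_dt = NA_real_,
                             time_unit = "model units", probe_time = NA_real_,
                             input_var = v_var) {
  structure(
    list(name = name, kind = kind, params = params, state0 = state0,
         v_var = v_var, map_step = map_step, derivs = derivs, events = events,
         gating_idx = gating_idx, native_dt = native_dt, time_unit = time_unit,
         probe_time = probe_time, input_var = input_var),
    class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model> %s (%s)\n", x$name, x$kind))
  cat("  state:", paste(names(x$state0), collapse = ", "), "\n")
  cat("  params:", paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @rdname neuron_models
#' @details
#' `neuron_rulkov()` builds the two-dimensional spiking-bursting map with a
#' piecewise fast variable and a slow variable moving at rate `mu`.  One map
#' iteration advances one "map point"; the calibration layer interpolates map
#' points up to the acquisition sampling rate.
#' @export
neuron_rulkov <- function(alpha = 5, sigma = 0.05, mu = 0.001,
                          x0 = -1.5, y0 = -3) {
  if (mu < 0) stop_bad("`mu` must be >= 0")
  params <- list(alpha = alpha, sigma = sigma, mu = mu)
  state0 <- c(x = x0, x_prev = x0, y = y0)
  new_neuron_model(
    name = "rulkov", kind = "map", params = params, state0 = state0,
    v_var = "x",
    map_step = function(state, input) rulkov_step(params, state, input),
    probe_time = 6000)
}

#' One iteration of the Rulkov spiking-bursting map
#'
#' Advances the piecewise fast map and the slow variable by one step.  The
#' external input is added to the slow variable's contribution to the fast
#' map (`y_eff = y + input`), the convention used when injecting synaptic
#' current into the map.
#'
#' @param params List with `alpha`, `sigma`, `mu`.
#' @param state Named numeric vector `(x, x_prev, y)`.
#' @param input Dimensionless injected input (default 0).
#' @return The updated state vector.
#' @export
rulkov_step <- function(params, state, input = 0) {
  assert_finite(state)
  assert_finite(input)
  x <- state[["x"]]; xp <- state[["x_prev"]]; y <- state[["y"]]
  y_eff <- y + input
  if (x <= 0) {
    if (x == 1) stop_bad("singular fast map at x == 1")
    x_new <- params$alpha / (1 - x) + y_eff
  } else if (x < params$alpha + y_eff && xp <= 0) {
    x_new <- params$alpha + y_eff
  } else {
    x_new <- -1
  }
  y_new <- y - params$mu * (x + 1) + params$mu * params$sigma
  c(x = x_new, x_prev = x, y = y_new)
}

#' @rdname neuron_models
#' @param a,b,c,d Izhikevich recovery rate (1/ms), sensitivity, reset voltage
#'   (mV) and recovery increment; `peak` is the spike-cut threshold (mV) and
#'   `I` a constant drive.  The defaults are a regularly bursting
#'   ("chattering") set.
#' @param I Constant injected drive (model current units).
#' @export
neuron_izhikevich <- function(a = 0.028, b = 0.2, c = -50, d = 2,
                              peak = 30, I = 15) {
  params <- list(a = a, b = b, c = c, d = d, peak = peak, I = I)
  v0 <- -65
  state0 <- c(v = v0, u = b * v0)
  new_neuron_model(
    name = "izhikevich", kind = "ode", params = params, state0 = state0,
    v_var = "v",
    derivs = function(state, t, input = 0) {
      v <- state[[1L]]; u <- state[[2L]]
      c(0.04 * v * v + 5 * v + 140 - u + params$I + input,
        a * (b * v - u))
    },
    events = function(state) {
      if (state[[1L]] >= params$peak) {
        state[[1L]] <- params$c
        state[[2L]] <- state[[2L]] + params$d
        list(state = state, fired = TRUE)
      } else {
        list(state = state, fired = FALSE)
      }
    },
    native_dt = 0.05, time_unit = "ms", probe_time = 3000)
}

#' @rdname neuron_models
#' @param r,s,x_rest Hindmarsh-Rose slow rate, slow gain and rest level; `b`
#'   the fast nonlinearity coefficient.  Defaults give regular square-wave
#'   bursting.
#' @export
neuron_hindmarsh_rose <- function(b = 3, I = 2.5, r = 0.004, s = 4,
                                  x_rest = -1.6) {
  if (r <= 0) stop_bad("`r` must be > 0")
  params <- list(b = b, I = I, r = r, s = s, x_rest = x_rest)
  state0 <- c(x = -1.5, y = -10, z = 2.6)
  new_neuron_model(
    name = "hindmarsh_rose", kind = "ode", params = params, state0 = state0,
    v_var = "x",
    derivs = function(state, t, input = 0) {
      x <- state[[1L]]; y <- state[[2L]]; z <- state[[3L]]
      c(y + b * x * x - x * x * x - z + params$I + input,
        1 - 5 * x * x - y,
        r * (s * (x - x_rest) - z))
    },
    native_dt = 0.02, probe_time = 3000)
}

#' @rdname neuron_models
#' @param variant Which minimal conductance-based burster to build:
#'   `"ghigliazza_holmes"` (Morris-Lecar-style fast subsystem with
#'   instantaneous Ca activation, a fast K gate and a slow KS gate, Boltzmann
#'   steady states) or `"wang"` (Hodgkin-Huxley-type spiker with exponential
#'   rate functions plus a slow K adaptation gate).
#' @param ... Parameter overrides for the chosen variant (see
#'   `neuron_preset()` for the shipped values).
#' @export
neuron_conductance <- function(variant = c("ghigliazza_holmes", "wang"), ...) {
  variant <- match.arg(variant)
  switch(variant,
         ghigliazza_holmes = neuron_ghigliazza_holmes(...),
         wang = neuron_wang(...))
}

boltzmann <- function(v, half, slope) 1 / (1 + exp(-(v - half) / slope))

#' @rdname neuron_models
#' @param C Membrane capacitance (uF/cm^2).
#' @param g_ca,g_k,g_ks,g_l Maximal conductances (mS/cm^2).
#' @param e_ca,e_k,e_l Reversal potentials (mV).
#' @param vm_half,vm_slope,vw_half,vw_slope,vc_half,vc_slope Boltzmann
#'   half-activation (mV) and slope (mV) of the Ca, fast-K and slow-KS gates.
#' @param tau_w,tau_c Gate time constants (ms); `tau_c` applies at
#'   depolarised voltages.
#' @param tau_c_rest KS gate time constant (ms) at hyperpolarised voltages;
#'   the two blend through a Boltzmann of `v` centred on `vc_half`.  Faster
#'   recovery at rest shortens the interburst interval without changing the
#'   burst itself (deinactivation-like kinetics).
#' @param use_tables Tabulate the Boltzmann steady states with a high
#'   resolution lookup table instead of evaluating the exponentials directly.
#' @details
#' The shipped `ghigliazza_holmes`-style default set places the fast
#' (v, w) subsystem in a bistable regime (coexisting rest state and
#' depolarised spiking) and lets the slow KS gate sweep across it, producing
#' regular square-wave bursting (~1 s bursts, ~3 s period in model time).
#' @export
neuron_ghigliazza_holmes <- function(C = 20, g_ca = 3.6, g_k = 6, g_ks = 4,
                                     g_l = 0.1, e_ca = 25, e_k = -75,
                                     e_l = -40, I = 1,
                                     vm_half = -24, vm_slope = 4.5,
                                     vw_half = -12, vw_slope = 4,
                                     vc_half = -40, vc_slope = 2,
                                     tau_w = 15, tau_c = 1600,
                                     tau_c_rest = 500,
                                     use_tables = FALSE) {
  params <- list(C = C, g_ca = g_ca, g_k = g_k, g_ks = g_ks, g_l = g_l,
                 e_ca = e_ca, e_k = e_k, e_l = e_l, I = I,
                 vm_half = vm_half, vm_slope = vm_slope,
                 vw_half = vw_half, vw_slope = vw_slope,
                 vc_half = vc_half, vc_slope = vc_slope,
                 tau_w = tau_w, tau_c = tau_c, tau_c_rest = tau_c_rest)
  minf <- function(v) boltzmann(v, vm_half, vm_slope)
  winf <- function(v) boltzmann(v, vw_half, vw_slope)
  cinf <- function(v) boltzmann(v, vc_half, vc_slope)
  if (use_tables) {
    minf <- table_fun(tabulate_fn(minf, -120, 80, 10001))
    winf <- table_fun(tabulate_fn(winf, -120, 80, 10001))
    cinf <- table_fun(tabulate_fn(cinf, -120, 80, 10001))
  }
  dtau <- tau_c - tau_c_rest
  state0 <- c(v = -60, w = 0, cs = 0.2)
  new_neuron_model(
    name = "ghigliazza_holmes", kind = "ode", params = params, state0 = state0,
    v_var = "v",
    derivs = function(state, t, input = 0) {
      v <- state[[1L]]; w <- state[[2L]]; cs <- state[[3L]]
      i_ion <- g_ca * minf(v) * (v - e_ca) + g_k * w * (v - e_k) +
        g_ks * cs * (v - e_k) + g_l * (v - e_l)
      tc_v <- tau_c_rest + dtau / (1 + exp(-(v - vc_half) / 4))
      c((I + input - i_ion) / C,
        (winf(v) - w) / tau_w,
        (cinf(v) - cs) / tc_v)
    },
    gating_idx = 2:3, native_dt = 0.1, time_unit = "ms", probe_time = 4e4)
}

#' @rdname neuron_models
#' @param g_na,e_na Sodium conductance (mS/cm^2) and reversal (mV) for the
#'   Hodgkin-Huxley-type variant.
#' @param vq_half,vq_slope,tau_q Slow K adaptation gate Boltzmann parameters
#'   and time constant (ms).
#' @details
#' The `wang` variant is a Hodgkin-Huxley-type model with the classic
#' exponential rate functions (full m, h, n gates) plus a slow potassium
#' adaptation gate.  The spiking core is bistable near its subcritical Hopf
#' onset, and the slow gate sweeping the effective drive across that window
#' yields regular elliptic bursting at roughly the pyloric rate in model
#' time (~0.5 s bursts, ~1.3 s period).  It is the most expensive model in
#' the library; its rate functions are the natural target for tabulation.
#' @export
neuron_wang <- function(C = 1, g_na = 120, g_k = 36, g_l = 0.3, g_ks = 2,
                        e_na = 50, e_k = -77, e_l = -54.4, I = 12,
                        vq_half = -30, vq_slope = 5, tau_q = 300,
                        use_tables = FALSE) {
  params <- list(C = C, g_na = g_na, g_k = g_k, g_l = g_l, g_ks = g_ks,
                 e_na = e_na, e_k = e_k, e_l = e_l, I = I,
                 vq_half = vq_half, vq_slope = vq_slope, tau_q = tau_q)
  # x/(1 - exp(-x)) with its removable singularity at 0
  xexp <- function(x) if (abs(x) < 1e-9) 1 + x / 2 else x / (1 - exp(-x))
  alpha_m <- function(v) xexp((v + 40) / 10)
  beta_m <- function(v) 4 * exp(-(v + 65) / 18)
  alpha_h <- function(v) 0.07 * exp(-(v + 65) / 20)
  beta_h <- function(v) 1 / (1 + exp(-(v + 35) / 10))
  alpha_n <- function(v) 0.1 * xexp((v + 55) / 10)
  beta_n <- function(v) 0.125 * exp(-(v + 65) / 80)
  qinf <- function(v) boltzmann(v, vq_half, vq_slope)
  if (use_tables) {
    alpha_m <- table_fun(tabulate_fn(alpha_m, -120, 60, 10001))
    beta_m <- table_fun(tabulate_fn(beta_m, -120, 60, 10001))
    alpha_h <- table_fun(tabulate_fn(alpha_h, -120, 60, 10001))
    beta_h <- table_fun(tabulate_fn(beta_h, -120, 60, 10001))
    alpha_n <- table_fun(tabulate_fn(alpha_n, -120, 60, 10001))
    beta_n <- table_fun(tabulate_fn(beta_n, -120, 60, 10001))
    qinf <- table_fun(tabulate_fn(qinf, -120, 60, 10001))
  }
  state0 <- c(v = -65, m = 0.05, h = 0.6, n = 0.32, q = 0)
  new_neuron_model(
    name = "wang", kind = "ode", params = params, state0 = state0,
    v_var = "v",
    derivs = function(state, t, input = 0) {
      v <- state[[1L]]; m <- state[[2L]]; h <- state[[3L]]
      n <- state[[4L]]; q <- state[[5L]]
      i_ion <- g_na * m^3 * h * (v - e_na) + g_k * n^4 * (v - e_k) +
        g_ks * q * (v - e_k) + g_l * (v - e_l)
      c((I + input - i_ion) / C,
        alpha_m(v) * (1 - m) - beta_m(v) * m,
        alpha_h(v) * (1 - h) - beta_h(v) * h,
        alpha_n(v) * (1 - n) - beta_n(v) * n,
        (qinf(v) - q) / tau_q)
    },
    gating_idx = 2:5, native_dt = 0.05, time_unit = "ms", probe_time = 13000)
}

#' Evaluate an ODE model's derivative vector
#'
#' Pure wrapper around a model's derivative function: no state is mutated and
#' the returned vector has the model's state layout.
#'
#' @param model A `neuron_model` of kind `"ode"`.
#' @param state Numeric state vector matching the model's layout.
#' @param t Model time (unused by the autonomous library models).
#' @param input Injected current in model units (added to the voltage
#'   equation).
#' @return Numeric vector of time derivatives.
#' @export
ode_derivs <- function(model, state, t = 0, input = 0) {
  if (!inherits(model, "neuron_model") || model$kind != "ode") {
    stop_bad("`model` must be a neuron_model of kind 'ode'")
  }
  if (length(state) != length(model$state0)) {
    stop_bad(sprintf("state has length %d, model '%s' expects %d",
                     length(state), model$name, length(model$state0)))
  }
  model$derivs(state, t, input)
}

#' Apply a model's discrete reset events
#'
#' After an integration step, models with a spike-cut rule (Izhikevich) reset
#' their state when the voltage reaches the peak threshold; the boundary is
#' inclusive (`v >= peak` fires).  Models without discrete events return the
#' state unchanged.
#'
#' @inheritParams ode_derivs
#' @return A list with elements `state` and `fired`.
#' @export
apply_discrete_events <- function(model, state) {
  if (is.null(model$events)) return(list(state = state, fired = FALSE))
  model$events(state)
}
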