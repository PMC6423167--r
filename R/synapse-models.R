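#' Synapse model library
#'
#' Coupling models for hybrid circuits, all computed in physiological units
#' (conductance in uS, voltage in mV, current in nA): an ohmic electrical
#' (gap-junction) synapse, graded chemical synapses whose release varies
#' continuously with presynaptic voltage (instantaneous "fast" mode or
#' first-order kinetic "slow" mode), and a spike-triggered chemical synapse
#' with transmitter-pulse kinetics.
#'
#' Graded-synapse thresholds and slopes are expressed as percentages of the
#' presynaptic signal's amplitude range, the convention used when coupling to
#' a living neuron whose absolute voltages are only known after calibration.
#'
#' @name synapse_models
NULL

new_synapse <- function(type, params) {
  structure(c(list(type = type), params), class = "synapse_model")
}

#' @export
print.synapse_model <- function(x, ...) {
  p <- x[setdiff(names(x), "type")]
  p <- p[vapply(p, is.numeric, logical(1))]
  cat(sprintf("<synapse_model> %s: %s\n", x$type,
              paste(sprintf("%s=%g", names(p), unlist(p)), collapse = ", ")))
  invisible(x)
}

#' @rdname synapse_models
#' @param g Maximal conductance (uS).
#' @export
synapse_electrical <- function(g) {
  if (g < 0) stop_bad("`g` must be >= 0")
  new_synapse("electrical", list(g = g))
}

#' @rdname synapse_models
#' @param v_threshold_pct,slope_pct Release threshold and slope as a
#'   percentage of the presynaptic amplitude range.
#' @param e_syn Reversal potential (mV); `NA` means "resolve to the observed
#'   minimum of the postsynaptic signal" at calibration time (guarantees an
#'   inhibitory driving force).
#' @param k1,k2 Forward/backward kinetic rates (1/s) of the slow mode.
#' @param mode `"fast"` (instantaneous activation) or `"slow"` (first-order
#'   gate).
#' @export
synapse_graded <- function(g, v_threshold_pct, slope_pct, e_syn = NA_real_,
                           k1 = 14, k2 = 4, mode = c("fast", "slow")) {
  mode <- match.arg(mode)
  if (g < 0) stop_bad("`g` must be >= 0")
  new_synapse(paste0("graded_", mode),
              list(g = g, v_threshold_pct = v_threshold_pct,
                   slope_pct = slope_pct, e_syn = e_syn,
                   k1 = k1, k2 = k2, mode = mode))
}

#' @rdname synapse_models
#' @param alpha,beta Transmitter binding (1/(ms*mM)) and unbinding (1/ms)
#'   rates of the spike-triggered chemical synapse.
#' @param t_max Transmitter pulse amplitude (mM).
#' @param pulse_duration Transmitter pulse duration after each presynaptic
#'   spike (ms).
#' @export
synapse_chemical <- function(g, e_syn, alpha = 0.94, beta = 0.18,
                             t_max = 1, pulse_duration = 1) {
  if (g < 0) stop_bad("`g` must be >= 0")
  new_synapse("chemical", list(g = g, e_syn = e_syn, alpha = alpha,
                               beta = beta, t_max = t_max,
                               pulse_duration = pulse_duration))
}

#' Electrical synapse current
#'
#' Ohmic gap-junction current `I = g * (v_pre - v_post)` in nA; exchanging
#' the two voltages negates the result.
#'
#' @param params A `synapse_model` from [synapse_electrical()] (or any list
#'   with a conductance `g` in uS).
#' @param v_pre,v_post Pre-/postsynaptic membrane potential (mV).
#' @return Current in nA flowing into the postsynaptic cell.
#' @export
electrical_current <- function(params, v_pre, v_post) {
  assert_finite(v_pre); assert_finite(v_post)
  params$g * (v_pre - v_post)
}

#' Graded release activation
#'
#' Boltzmann activation of a graded synapse,
#' `1 / (1 + exp((v_th - v_pre)/s))`, with threshold and slope resolved
#' against the presynaptic amplitude range:
#' `v_th = min + pct_th * (max - min)`, `s = pct_s * (max - min)`.
#' Activation is exactly 0.5 at the absolute threshold and monotone
#' non-decreasing in `v_pre`.
#'
#' @param params A graded `synapse_model`.
#' @param v_pre Presynaptic voltage (mV).
#' @param pre_range Length-2 numeric `(min, max)` of the presynaptic signal
#'   (mV), typically from calibration.
#' @return Activation in `[0, 1]`.
#' @export
graded_activation <- function(params, v_pre, pre_range) {
  rng <- pre_range[2] - pre_range[1]
  if (!(rng > 0)) stop_bad("degenerate presynaptic range (min >= max)")
  v_th <- pre_range[1] + params$v_threshold_pct / 100 * rng
  s <- params$slope_pct / 100 * rng
  1 / (1 + exp((v_th - v_pre) / s))
}

#' Advance the slow graded gate one step
#'
#' First-order release kinetics `dm/dt = k1 * (1 - m) * a - k2 * m` with
#' activation `a` from [graded_activation()]; the fixed point at constant
#' activation is `m* = k1*a / (k1*a + k2)`.  The step uses the exact
#' exponential update of the (locally constant-coefficient) linear equation,
#' so the gate cannot leave `[0, 1]` for any step size.
#'
#' @inheritParams graded_activation
#' @param m_gate Current gate value in `[0, 1]`.
#' @param dt Time step (s); rates `k1`, `k2` are in 1/s.
#' @return Updated gate value.
#' @export
graded_slow_step <- function(params, m_gate, v_pre, pre_range, dt) {
  assert_scalar_pos(dt)
  if (m_gate < 0 || m_gate > 1) stop_bad("`m_gate` must lie in [0, 1]")
  a <- graded_activation(params, v_pre, pre_range)
  rate <- params$k1 * a + params$k2
  m_inf <- if (rate > 0) params$k1 * a / rate else m_gate
  m_inf + (m_gate - m_inf) * exp(-rate * dt)
}

#' Graded synapse current
#'
#' `I = g * gate * (v_post - e_syn)` in nA, with the convention that positive
#' current is withdrawn from the postsynaptic cell (inhibitory whenever
#' `e_syn` sits below `v_post`).
#'
#' @inheritParams graded_activation
#' @param gate Gate/activation value in `[0, 1]` (instantaneous activation
#'   for fast synapses, the kinetic gate for slow ones).
#' @param v_post Postsynaptic voltage (mV).
#' @param e_syn Reversal potential (mV); defaults to the value stored in
#'   `params`.
#' @export
graded_current <- function(params, gate, v_post, e_syn = params$e_syn) {
  if (gate < 0 || gate > 1) stop_bad("`gate` must lie in [0, 1]")
  params$g * gate * (v_post - e_syn)
}

#' Advance the spike-triggered chemical synapse
#'
#' Transmitter concentration is a square pulse: `T = t_max` within
#' `pulse_duration` (ms) after the most recent presynaptic spike, else 0.
#' The open fraction follows `ds/dt = alpha * T * (1 - s) - beta * s`
#' (exact exponential update over the step) and the current is
#' `I = g * s * (v_post - e_syn)`.
#'
#' @inheritParams graded_current
#' @param s_open Current open fraction in `[0, 1]`.
#' @param spike_times Sorted presynaptic spike times (ms).
#' @param t_now Current time (ms).
#' @param dt Step (ms).
#' @return List with `s_open` (updated) and `current` (nA).
#' @export
chemical_step <- function(params, s_open, spike_times, t_now, v_post, dt) {
  if (length(spike_times) > 1 && is.unsorted(spike_times)) {
    stop_bad("`spike_times` must be sorted increasingly")
  }
  last <- if (length(spike_times)) {
    prev <- spike_times[spike_times <= t_now + dt]
    if (length(prev)) prev[length(prev)] else -Inf
  } else -Inf
  trans <- if (is.finite(last) && (t_now + dt) - last <= params$pulse_duration)
    params$t_max else 0
  rate <- params$alpha * trans + params$beta
  s_inf <- if (rate > 0) params$alpha * trans / rate else 0
  s_new <- s_inf + (s_open - s_inf) * exp(-rate * dt)
  list(s_open = s_new,
       current = params$g * s_new * (v_post - params$e_syn))
}

#' Detect presynaptic spikes by threshold crossing
#'
#' Upward crossings of `threshold` with a refractory hold: crossings closer
#' than `refractory` to the previous accepted spike are ignored.
#'
#' @param trace Trace data frame (`time`, `v`) or numeric voltage vector.
#' @param threshold Crossing level (mV).
#' @param refractory Minimum spacing between spikes (same unit as time).
#' @param fs Sampling rate, required when `trace` is a bare vector.
#' @return Tibble with one row per spike (`time`, `index`).
#' @export
detect_spikes <- function(trace, threshold, refractory = 0.002, fs = NULL) {
  tr <- as_trace(trace, fs)
  v <- tr$v
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  keep <- integer(0)
  last_t <- -Inf
  for (i in up) {
    if (tr$time[i] - last_t >= refractory) {
      keep <- c(keep, i)
      last_t <- tr$time[i]
    }
  }
  tibble::tibble(time = tr$time[keep], index = keep)
}
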