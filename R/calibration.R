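#' Detect bursts in a membrane-potential trace
#'
#' Hysteresis thresholding on the slow depolarisation envelope: a burst
#' starts at an upward crossing of the onset threshold and ends at a downward
#' crossing of the (lower) offset threshold, both expressed as fractions of
#' the trace's amplitude range (`min + frac * (max - min)`).  Events closer
#' than `min_gap` are merged, so intra-burst spikes do not fragment a burst.
#' An optional running-mean smoother can be applied first when spikes are
#' large relative to the slow wave.
#'
#' @param trace Trace data frame with `time` and `v` columns (as returned by
#'   [free_run()] and friends) or a bare numeric voltage vector (then `fs` is
#'   required).
#' @param fs Sampling rate (Hz); inferred from the time column if omitted.
#' @param frac_threshold Onset/offset hysteresis fractions of the amplitude
#'   range; a single value is used for both.
#' @param min_gap Minimum quiescent gap between bursts (s); closer events are
#'   merged.
#' @param smooth Running-mean window (s) applied before thresholding; 0
#'   disables smoothing.
#' @return A tibble with one row per burst: `onset`, `offset`, `duration`
#'   (s), and `v_min`, `v_max` over the burst.  A flat trace yields zero
#'   rows.
#' @export
detect_bursts <- function(trace, fs = NULL, frac_threshold = c(0.25, 0.15),
                          min_gap = 0.1, smooth = 0) {
  tr <- as_trace(trace, fs)
  fs <- trace_fs(tr, fs)
  v_raw <- tr$v
  v <- v_raw
  if (smooth > 0) {
    w <- max(1L, round(smooth * fs))
    if (w > 1L) {
      v <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
      # running mean is NA at the edges; hold the boundary values
      n <- length(v)
      first <- which(!is.na(v))[1]
      last <- n + 1L - which(!is.na(rev(v)))[1]
      v[seq_len(first - 1L)] <- v[first]
      v[seq((last + 1L), length.out = n - last)] <- v[last]
    }
  }
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) {
    return(tibble::tibble(onset = numeric(0), offset = numeric(0),
                          duration = numeric(0), v_min = numeric(0),
                          v_max = numeric(0)))
  }
  fr <- rep_len(frac_threshold, 2L)
  if (any(fr <= 0) || any(fr >= 1)) stop_bad("`frac_threshold` must lie in (0, 1)")
  th_on <- lo + fr[1] * (hi - lo)
  th_off <- lo + fr[2] * (hi - lo)
  n <- length(v)
  onsets <- integer(0); offsets <- integer(0)
  inside <- v[1] >= th_on
  if (inside) onsets <- 1L
  for (i in 2:n) {
    if (!inside && v[i] >= th_on && v[i - 1L] < th_on) {
      inside <- TRUE; onsets <- c(onsets, i)
    } else if (inside && v[i] < th_off && v[i - 1L] >= th_off) {
      inside <- FALSE; offsets <- c(offsets, i)
    }
  }
  if (inside) onsets <- onsets[-length(onsets)]  # drop unterminated burst
  m <- min(length(onsets), length(offsets))
  if (m == 0L) {
    return(tibble::tibble(onset = numeric(0), offset = numeric(0),
                          duration = numeric(0), v_min = numeric(0),
                          v_max = numeric(0)))
  }
  onsets <- onsets[seq_len(m)]; offsets <- offsets[seq_len(m)]
  # merge events separated by less than min_gap
  keep_on <- onsets[1]; merged_on <- integer(0); merged_off <- integer(0)
  for (j in seq_len(m)) {
    if (j < m && (tr$time[onsets[j + 1L]] - tr$time[offsets[j]]) < min_gap) {
      next
    }
    merged_on <- c(merged_on, keep_on)
    merged_off <- c(merged_off, offsets[j])
    if (j < m) keep_on <- onsets[j + 1L]
  }
  tibble::tibble(
    onset = tr$time[merged_on],
    offset = tr$time[merged_off],
    duration = tr$time[merged_off] - tr$time[merged_on],
    v_min = vapply(seq_along(merged_on),
                   function(j) min(v_raw[merged_on[j]:merged_off[j]]), numeric(1)),
    v_max = vapply(seq_along(merged_on),
                   function(j) max(v_raw[merged_on[j]:merged_off[j]]), numeric(1)))
}

#' Affine amplitude map between model units and mV
#'
#' Two-point affine map sending the model's observed `(min, max)` onto the
#' living neuron's `(min, max)`: `v_mv = gain * v_model + offset`.  The
#' returned object also carries the exact inverse.
#'
#' @param model_range,live_range Length-2 numeric `(min, max)`; both must be
#'   non-degenerate.
#' @return An `amplitude_map` list with `gain`, `offset`, and ranges.
#' @export
fit_amplitude_map <- function(model_range, live_range) {
  if (!(model_range[2] > model_range[1]) || !(live_range[2] > live_range[1])) {
    stop_bad("degenerate range: min must be < max on both sides")
  }
  gain <- (live_range[2] - live_range[1]) / (model_range[2] - model_range[1])
  offset <- live_range[1] - gain * model_range[1]
  structure(list(gain = gain, offset = offset,
                 model_range = as.numeric(model_range),
                 live_range = as.numeric(live_range)),
            class = "amplitude_map")
}

#' @rdname fit_amplitude_map
#' @param map An `amplitude_map`.
#' @param v_model Model-unit voltages to map to mV.
#' @export
map_to_mv <- function(map, v_model) map$gain * v_model + map$offset

#' @rdname fit_amplitude_map
#' @param v_mv mV voltages to map back to model units.
#' @export
map_to_model <- function(map, v_mv) (v_mv - map$offset) / map$gain

#' Time-scale factor matching a model burst to a target duration
#'
#' For ODE models: the model time to advance per acquisition interval so a
#' burst lasting `model_burst` model-time units stretches over
#' `target_burst` seconds at `fs`.  For map models: the interpolation ratio
#' `r`, the number of output samples to emit per map point.
#'
#' @param model_burst Burst length in model-time units (ODE) or map points
#'   (map models).
#' @param target_burst Target burst duration (s).
#' @param fs Acquisition sampling rate (Hz).
#' @param kind `"ode"` or `"map"`.
#' @return Model-time per interval (ODE) or samples per map point (map).
#' @export
fit_time_scale <- function(model_burst, target_burst, fs,
                           kind = c("ode", "map")) {
  kind <- match.arg(kind)
  assert_scalar_pos(model_burst); assert_scalar_pos(target_burst)
  assert_scalar_pos(fs)
  if (kind == "ode") model_burst / (target_burst * fs)
  else target_burst * fs / model_burst
}

#' Interpolate map-model output up to the acquisition rate
#'
#' Emits linearly interpolated samples between two consecutive map points at
#' a long-run rate of exactly `r` samples per map point, using a phase
#' accumulator so non-integer ratios stay exact: over `N` map points the
#' emitted count is `floor(N*r)` or `ceiling(N*r)`.
#'
#' @param x_prev,x_next Consecutive map outputs.
#' @param r Samples per map point (> 0).
#' @param phase Phase accumulator in `[0, 1)` carried between calls (0 at the
#'   start of a stream; a sample at phase 0 reproduces `x_prev` exactly).
#' @return List with `samples` (numeric vector, possibly empty) and `phase`
#'   (the accumulator to pass to the next call).
#' @export
interpolate_map_output <- function(x_prev, x_next, r, phase = 0) {
  assert_scalar_pos(r)
  step <- 1 / r
  samples <- numeric(0)
  while (phase < 1 - 1e-12) {
    samples <- c(samples, x_prev + phase * (x_next - x_prev))
    phase <- phase + step
  }
  list(samples = samples, phase = phase - 1)
}

#' Drift compensation state
#'
#' Estimates slow baseline drift of the recorded signal from its per-window
#' floor: each window contributes a robust lower quantile (the raw minimum is
#' extreme-value noisy), the floor sequence is smoothed by a pair of
#' exponential moving averages whose combination `2*ema(tau) - ema(2*tau)`
#' cancels the tracking lag of a linear ramp, and the correction -- current
#' baseline minus the initial baseline (averaged over the first few windows)
#' -- is subtracted from the live signal before any threshold or range
#' computation.
#'
#' @param tau_s Smoothing time constant (s) of the primary EMA.
#' @param window_s Window length (s) over which each floor value is taken.
#' @param quantile Lower quantile defining the window floor.
#' @param init_windows Windows averaged into the initial baseline (the
#'   correction is 0 while it is being established).
#' @param enabled Logical; when `FALSE` the correction is always exactly 0.
#' @return A `drift_state` list.
#' @export
drift_state <- function(tau_s = 3, window_s = 1, quantile = 0.1,
                        init_windows = 3L, enabled = TRUE) {
  structure(list(tau_s = tau_s, window_s = window_s, quantile = quantile,
                 init_windows = as.integer(init_windows), enabled = enabled,
                 seen = 0L, init_sum = 0, initial = NA_real_,
                 e1 = NA_real_, e2 = NA_real_),
            class = "drift_state")
}

#' @rdname drift_state
#' @param state A `drift_state`.
#' @param window Numeric vector of voltage samples (mV) from the latest
#'   window.
#' @return List with the updated `state` and the current `correction` (mV).
#' @export
update_drift <- function(state, window) {
  if (!length(window)) stop_bad("`window` must be non-empty")
  if (!state$enabled) return(list(state = state, correction = 0))
  floor_v <- stats::quantile(window, state$quantile, names = FALSE)
  state$seen <- state$seen + 1L
  if (state$seen <= state$init_windows) {
    state$init_sum <- state$init_sum + floor_v
    if (state$seen == state$init_windows) {
      state$initial <- state$init_sum / state$init_windows
      state$e1 <- state$initial
      state$e2 <- state$initial
    }
    return(list(state = state, correction = 0))
  }
  a1 <- 1 - exp(-state$window_s / state$tau_s)
  a2 <- 1 - exp(-state$window_s / (2 * state$tau_s))
  state$e1 <- state$e1 + a1 * (floor_v - state$e1)
  state$e2 <- state$e2 + a2 * (floor_v - state$e2)
  list(state = state,
       correction = (2 * state$e1 - state$e2) - state$initial)
}

#' Calibrate a neuron model to a living neuron's range and rhythm
#'
#' Reproduces the automatic adaptation between a model and a living neuron:
#' a free run of the model in its native time base is burst-analysed to
#' obtain its amplitude range and mean burst duration; an affine amplitude
#' map onto the live range and a time-scale factor (model time per
#' acquisition interval, or interpolation ratio for map models) are then
#' fitted, and for ODE models a stable integration substep is selected for
#' the per-interval budget.
#'
#' @param model A `neuron_model`.
#' @param fs Acquisition sampling rate (Hz).
#' @param target_burst Target burst duration (s); 1 s is the conventional
#'   hybrid-circuit setting.
#' @param live_range Length-2 `(min, max)` mV range of the living neuron.
#' @param integrator An [integrator_spec()] for ODE stepping.
#' @param min_bursts Native-run bursts required for a reliable estimate.
#' @param frac_threshold,min_gap,smooth_frac Burst-detector settings used on
#'   the native trace (`smooth_frac` is the running-mean window as a fraction
#'   of the mean burst duration, applied in a second, refined pass).
#' @return A `calibration` object: amplitude map, time scale, substep
#'   selection, native burst statistics.
#' @export
calibrate_model <- function(model, fs, target_burst = 1,
                            live_range = c(-60, -25),
                            integrator = integrator_spec("rk4"),
                            min_bursts = 8, frac_threshold = c(0.25, 0.15),
                            min_gap = 0.1, smooth_frac = 0.05) {
  assert_scalar_pos(fs); assert_scalar_pos(target_burst)
  key <- paste(model$name, paste(signif(unlist(model$params), 12), collapse = ","),
               fs, target_burst, paste(live_range, collapse = ","),
               integrator$method, min_bursts, sep = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  native <- native_run(model, min_bursts = min_bursts,
                       frac_threshold = frac_threshold)
  bursts <- native$bursts
  if (nrow(bursts) < 3) {
    stop_bad(sprintf("calibration failed: only %d burst(s) detected in a %s-sample native run of '%s'",
                     nrow(bursts), length(native$v), model$name),
             class = "hybridclamp_calibration")
  }
  burst_dur <- mean(bursts$duration)      # native sample units
  period <- if (nrow(bursts) > 1) mean(diff(bursts$onset)) else NA_real_
  model_range <- range(native$v)
  amap <- fit_amplitude_map(model_range, live_range)
  if (model$kind == "map") {
    r <- fit_time_scale(burst_dur, target_burst, fs, kind = "map")
    scale <- list(r = r, dt_per_interval = NA_real_, n_substeps = NA_integer_)
  } else {
    dt_model <- burst_dur * model$native_dt  # model-time units
    dt_int <- fit_time_scale(dt_model, target_burst, fs, kind = "ode")
    sel <- select_step(integrator, model, dt_int,
                       probe_time = period * model$native_dt)
    scale <- list(r = NA_real_, dt_per_interval = dt_int,
                  n_substeps = sel$n_substeps)
  }
  out <- structure(list(model = model$name, kind = model$kind, fs = fs,
                        target_burst = target_burst, amplitude = amap,
                        time_scale = scale, state_ready = native$state_final,
                        native_burst = burst_dur, native_period = period,
                        native_range = model_range, integrator = integrator,
                        n_native_bursts = nrow(bursts)),
                   class = "calibration")
  .calib_cache[[key]] <- out
  out
}

# Calibration is deterministic in its inputs; cache the (expensive) native
# runs within a session.
.calib_cache <- new.env(parent = emptyenv())

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> model '%s' (%s) at %g Hz\n", x$model, x$kind, x$fs))
  cat(sprintf("  amplitude: gain %.4g, offset %.4g (model [%.3g, %.3g] -> live [%.3g, %.3g])\n",
              x$amplitude$gain, x$amplitude$offset,
              x$amplitude$model_range[1], x$amplitude$model_range[2],
              x$amplitude$live_range[1], x$amplitude$live_range[2]))
  if (x$kind == "map") {
    cat(sprintf("  time scale: r = %.4g samples per map point\n", x$time_scale$r))
  } else {
    cat(sprintf("  time scale: %.4g model-time per interval, %d substep(s)\n",
                x$time_scale$dt_per_interval, x$time_scale$n_substeps))
  }
  invisible(x)
}

# Run the model in its native time base until at least `min_bursts` bursts
# are detected (doubling the run length as needed).  Times in the returned
# burst table are in native samples (map points, or native_dt units).
native_run <- function(model, min_bursts = 8, frac_threshold = c(0.25, 0.15),
                       max_samples = 4e6) {
  n <- if (is.finite(model$probe_time)) {
    if (model$kind == "map") as.integer(model$probe_time)
    else as.integer(model$probe_time / model$native_dt)
  } else 100000L
  repeat {
    run <- free_run_native(model, n)
    # discard the settling transient before measuring the rhythm
    v <- run$v[-seq_len(floor(0.2 * n))]
    # sample-unit detector: fs = 1 so onset/duration come out in samples.
    # No smoothing: hysteresis plus the min_gap merge absorbs intra-burst
    # spikes (including spike troughs dipping under the offset threshold).
    bursts <- detect_bursts(v, fs = 1, frac_threshold = frac_threshold,
                            min_gap = max(50, 0.005 * n), smooth = 0)
    if (nrow(bursts) >= min_bursts || n >= max_samples) {
      return(list(v = v, bursts = bursts, n = n, state_final = run$state))
    }
    n <- min(max_samples, n * 2L)
  }
}

# Native free run: iterate the map, or integrate at native_dt, returning the
# designated voltage variable per native sample and the final state (a
# "warmed-up" state on the bursting attractor, past the settling transient).
free_run_native <- function(model, n_samples, input = 0) {
  v <- numeric(n_samples)
  state <- model$state0
  iv <- which(names(model$state0) == model$v_var)
  if (model$kind == "map") {
    step <- model$map_step
    for (k in seq_len(n_samples)) {
      state <- step(state, input)
      v[k] <- state[[iv]]
    }
  } else {
    for (k in seq_len(n_samples)) {
      state <- step_model(model, state, model$native_dt, 1L, "rk4", input)
      v[k] <- state[[iv]]
    }
  }
  list(v = v, state = state)
}
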