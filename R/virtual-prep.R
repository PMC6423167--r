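#' Virtual preparation: a synthetic living neuron behind a DAQ
#'
#' Stand-in for the biological side of a hybrid circuit: a calibrated
#' bursting neuron model (Hindmarsh-Rose by default) scaled to a
#' physiological mV range and a target burst period of about one burst per
#' second -- the characteristic rate of a pyloric CPG cell -- plus additive
#' Gaussian measurement noise and optional slow linear drift.  Injected
#' current is mapped into model units through the inverse amplitude map, so
#' dynamic-clamp currents computed in nA act on the intrinsic model.
#'
#' With noise and drift at zero and no injected current the output is
#' exactly the deterministic calibrated model trace.
#'
#' @param model Intrinsic `neuron_model` (bursting preset).
#' @param fs Sampling rate (Hz).
#' @param target_period_s Target burst period (s).
#' @param live_range Output voltage range (mV) the model is mapped onto.
#' @param noise_sd Additive Gaussian noise on the output sample (mV).
#' @param drift_mv_per_min Linear baseline drift (mV/minute).
#' @param soma_tau_s Electrotonic low-pass time constant (s) applied to the
#'   model trace before noise: somatic recordings of bursting CPG neurons
#'   show a dominant slow wave with strongly attenuated spikes (spikes are
#'   generated distally and filtered by the cable), and this one-pole filter
#'   reproduces that waveform.  Set to 0 for the raw mapped model trace.
#' @param replay Optional recorded trace to replay instead of the model: a
#'   data frame with `time` (s) and `v` (mV) columns; it is resampled to
#'   `fs` and recycled if shorter than the run.
#' @return A `virtual_preparation` object (stateful environment).
#' @export
virtual_preparation <- function(model = neuron_hindmarsh_rose(), fs = 10000,
                                target_period_s = 1, live_range = c(-60, -25),
                                noise_sd = 0.5, drift_mv_per_min = 0,
                                soma_tau_s = 0.02, replay = NULL) {
  prep <- new.env(parent = emptyenv())
  prep$fs <- fs
  prep$noise_sd <- noise_sd
  prep$drift_rate <- drift_mv_per_min / 60   # mV per second
  prep$live_range <- live_range
  prep$t <- 0
  prep$lp_alpha <- if (soma_tau_s > 0) 1 - exp(-1 / (fs * soma_tau_s)) else 1
  prep$v_f <- NA_real_
  if (!is.null(replay)) {
    tr <- as_trace(replay)
    prep$mode <- "replay"
    prep$replay_v <- resample_trace(tr, fs)
    prep$replay_i <- 0L
    prep$amplitude <- fit_amplitude_map(range(tr$v), range(tr$v))  # identity
  } else {
    prep$mode <- "model"
    # period-based calibration: the preparation is characterised by its
    # burst *rate*, so model time is scaled so one native period spans
    # target_period_s
    cal <- calibrate_model(model, fs, target_burst = 1, live_range = live_range)
    prep$model <- model
    prep$iv <- which(names(model$state0) == model$v_var)
    prep$method <- cal$integrator$method
    ready <- if (!is.null(cal$state_ready)) cal$state_ready else model$state0
    if (model$kind == "map") {
      prep$r <- target_period_s * fs / cal$native_period
      prep$phase <- 0
      prep$x_prev <- ready[[prep$iv]]
      prep$state <- model$map_step(ready, 0)
    } else {
      period_model <- cal$native_period * model$native_dt
      dt_int <- period_model / (target_period_s * fs)
      sel <- select_step(cal$integrator, model, dt_int,
                         probe_time = period_model)
      prep$dt_int <- dt_int
      prep$n_sub <- sel$n_substeps
      prep$state <- ready
    }
    prep$amplitude <- cal$amplitude
  }
  class(prep) <- "virtual_preparation"
  prep
}

#' @export
print.virtual_preparation <- function(x, ...) {
  cat(sprintf("<virtual_preparation> %s at %g Hz, noise %g mV, drift %g mV/s\n",
              if (x$mode == "replay") "replayed trace" else x$model$name,
              x$fs, x$noise_sd, x$drift_rate))
  invisible(x)
}

#' Advance the virtual preparation one acquisition interval
#'
#' @param prep A [virtual_preparation()].
#' @param injected_current Dynamic-clamp current (nA); positive is
#'   depolarising.
#' @param dt Interval length (s); normally `1/fs`.
#' @return Membrane voltage sample (mV), noise and drift included.
#' @export
prep_step <- function(prep, injected_current = 0, dt = 1 / prep$fs) {
  if (!is.finite(injected_current)) {
    stop_bad("`injected_current` must be finite", class = "hybridclamp_nonfinite")
  }
  if (prep$mode == "replay") {
    prep$replay_i <- prep$replay_i + 1L
    v_mv <- prep$replay_v[((prep$replay_i - 1L) %% length(prep$replay_v)) + 1L]
  } else {
    input <- injected_current / prep$amplitude$gain
    model <- prep$model
    if (model$kind == "map") {
      # emit one interpolated sample per interval, advancing the map when
      # the phase accumulator wraps
      if (prep$phase >= 1) {
        prep$phase <- prep$phase - 1
        prep$x_prev <- prep$state[[prep$iv]]
        prep$state <- model$map_step(prep$state, input)
      }
      x_next <- prep$state[[prep$iv]]
      v_model <- prep$x_prev + prep$phase * (x_next - prep$x_prev)
      prep$phase <- prep$phase + 1 / prep$r
    } else {
      prep$state <- step_model(model, prep$state, prep$dt_int, prep$n_sub,
                               prep$method, input = input)
      v_model <- prep$state[[prep$iv]]
    }
    v_mv <- map_to_mv(prep$amplitude, v_model)
  }
  # electrotonic (somatic) filtering of the intracellular waveform
  if (is.na(prep$v_f)) prep$v_f <- v_mv
  prep$v_f <- prep$v_f + prep$lp_alpha * (v_mv - prep$v_f)
  prep$t <- prep$t + dt
  drift <- prep$drift_rate * prep$t
  noise <- if (prep$noise_sd > 0) stats::rnorm(1L, 0, prep$noise_sd) else 0
  prep$v_f + drift + noise
}

#' Run the preparation freely for a stretch of time
#'
#' Convenience wrapper advancing [prep_step()] sample by sample with a
#' constant (default zero) injected current.
#'
#' @inheritParams prep_step
#' @param duration_s Run length (s).
#' @return Tibble with `time` (s) and `v` (mV).
#' @export
prep_run <- function(prep, duration_s, injected_current = 0) {
  n <- as.integer(round(duration_s * prep$fs))
  v <- numeric(n)
  for (k in seq_len(n)) v[k] <- prep_step(prep, injected_current)
  tibble::tibble(time = (seq_len(n) - 1) / prep$fs, v = v)
}

#' Acquisition scaling of the DAQ boundary
#'
#' Linear conversions at the acquisition boundary: the amplifier's output
#' voltage is multiplied by `input_factor` to recover membrane mV, and a
#' command voltage is converted to injected current at `na_per_v`.
#'
#' @param input_factor Dimensionless input voltage scaling (default 100).
#' @param na_per_v Output current conversion (nA per command volt,
#'   default 10).
#' @return An `acquisition_scaling` object.
#' @export
acquisition_scaling <- function(input_factor = 100, na_per_v = 10) {
  structure(list(input_factor = input_factor, na_per_v = na_per_v),
            class = "acquisition_scaling")
}

#' @rdname acquisition_scaling
#' @param scaling An `acquisition_scaling`.
#' @param raw_in Raw acquired voltage (V).
#' @param command_out Command voltage (V).
#' @return List with `v_membrane` (mV) and `i_injected` (nA).
#' @export
daq_exchange <- function(scaling, raw_in, command_out) {
  assert_finite(raw_in); assert_finite(command_out)
  list(v_membrane = scaling$input_factor * raw_in,
       i_injected = scaling$na_per_v * command_out)
}

resample_trace <- function(tr, fs) {
  t_end <- max(tr$time)
  tt <- seq(0, t_end, by = 1 / fs)
  stats::approx(tr$time, tr$v, xout = tt, rule = 2)$y
}
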