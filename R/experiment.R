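#' Calibrated free run of a neuron model
#'
#' Streams a model through its calibration -- time scale matched to the
#' target burst duration, amplitude mapped onto the live mV range -- at the
#' acquisition sampling rate, with no coupling.
#'
#' @param model A `neuron_model` or preset name.
#' @param duration_s Run length (s).
#' @param fs Sampling rate (Hz).
#' @param calibration A `calibration` from [calibrate_model()]; computed
#'   with the defaults when omitted.
#' @param ... Passed to [calibrate_model()] when `calibration` is `NULL`.
#' @return Tibble with `time` (s) and `v` (mV).
#' @export
free_run <- function(model, duration_s, fs = 10000, calibration = NULL, ...) {
  if (is.character(model)) model <- neuron_preset(model)
  if (is.null(calibration)) calibration <- calibrate_model(model, fs, ...)
  n <- as.integer(round(duration_s * fs))
  v <- stream_samples(model, calibration, n)
  tibble::tibble(time = (seq_len(n) - 1) / fs, v = v)
}

# One-sample-per-call streaming interface over a calibrated model: takes the
# injected current in nA, returns the next membrane sample in mV.  This is
# the "neuron model" operation of the loop interval.
model_streamer <- function(model, cal, st = new_stream_state(model, cal)) {
  amap <- cal$amplitude
  gain <- amap$gain
  offset <- amap$offset
  lo <- amap$live_range[1]; hi <- amap$live_range[2]
  iv <- which(names(model$state0) == model$v_var)
  if (model$kind == "map") {
    r <- cal$time_scale$r
    step <- model$map_step
    function(i_na) {
      if (st$phase >= 1) {
        st$phase <- st$phase - 1
        st$x_prev <- st$state[[iv]]
        st$state <- step(st$state, i_na / gain)
      }
      x_next <- st$state[[iv]]
      v <- st$x_prev + st$phase * (x_next - st$x_prev)
      st$phase <- st$phase + 1 / r
      v <- gain * v + offset
      if (v < lo) lo else if (v > hi) hi else v
    }
  } else {
    dt_int <- cal$time_scale$dt_per_interval
    n_sub <- cal$time_scale$n_substeps
    method <- cal$integrator$method
    function(i_na) {
      st$state <- step_model(model, st$state, dt_int, n_sub, method,
                             input = i_na / gain)
      v <- gain * st$state[[iv]] + offset
      if (v < lo) lo else if (v > hi) hi else v
    }
  }
}

new_stream_state <- function(model, cal = NULL) {
  st <- new.env(parent = emptyenv())
  # start from the calibration's warmed-up state (on the bursting attractor)
  # so a stream shows the established rhythm from its first sample
  state0 <- if (!is.null(cal) && !is.null(cal$state_ready)) cal$state_ready
            else model$state0
  if (model$kind == "map") {
    st$phase <- 0
    st$x_prev <- state0[[which(names(model$state0) == model$v_var)]]
    st$state <- model$map_step(state0, 0)
  } else {
    st$state <- unname(state0)
  }
  st
}

# Vectorised-uncoupled fast path: emit n free-running samples.
stream_samples <- function(model, cal, n, st = new_stream_state(model, cal)) {
  v <- numeric(n)
  gain <- cal$amplitude$gain; offset <- cal$amplitude$offset
  rng <- cal$amplitude$live_range
  iv <- which(names(model$state0) == model$v_var)
  if (model$kind == "map") {
    r <- cal$time_scale$r
    step <- model$map_step
    phase <- st$phase; x_prev <- st$x_prev; state <- st$state
    for (k in seq_len(n)) {
      if (phase >= 1) {
        phase <- phase - 1
        x_prev <- state[[iv]]
        state <- step(state, 0)
      }
      v[k] <- x_prev + phase * (state[[iv]] - x_prev)
      phase <- phase + 1 / r
    }
    st$phase <- phase; st$x_prev <- x_prev; st$state <- state
  } else {
    h <- cal$time_scale$dt_per_interval / cal$time_scale$n_substeps
    n_sub <- cal$time_scale$n_substeps
    method <- cal$integrator$method
    f <- model$derivs; ev <- model$events
    state <- st$state
    for (k in seq_len(n)) {
      for (s in seq_len(n_sub)) {
        state <- rk_substep(f, ev, state, h, method, 0)
      }
      v[k] <- state[[iv]]
    }
    st$state <- state
  }
  pmin(pmax(v * gain + offset, rng[1]), rng[2])
}

# One fixed substep, inlined per method; shared by the fused experiment
# engine and the free-run streamer (identical arithmetic to step_model).
rk_substep <- function(f, ev, state, h, method, input) {
  k1 <- f(state, 0, input)
  if (method == "euler") {
    state <- state + h * k1
  } else if (method == "heun") {
    k2 <- f(state + h * k1, 0, input)
    state <- state + h * 0.5 * (k1 + k2)
  } else {
    k2 <- f(state + h / 2 * k1, 0, input)
    k3 <- f(state + h / 2 * k2, 0, input)
    k4 <- f(state + h * k3, 0, input)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (!is.null(ev)) state <- ev(state)$state
  state
}

#' Run a full hybrid-circuit experiment
#'
#' Executes the control-coupled-control protocol against the virtual
#' preparation: a pre-control phase records the uncoupled living neuron,
#' calibration fits the model's amplitude map and time scale to the observed
#' live range and burst duration, the coupled phase runs both neurons inside
#' the periodic loop with the two graded synapses active (per-interval
#' operation order: DAQ exchange, drift compensation, synapses, neuron
#' model, enqueue), and a post-control phase records both units uncoupled
#' again.  Synaptic currents are exactly zero outside the coupled phase.
#'
#' Two engines produce identical results on the virtual clock: the generic
#' task loop of [run_loop()] (`engine = "loop"`, always used on the wall
#' clock) and a fused single-function loop (`engine = "fused"`) that executes
#' the same operations in the same order with the loop bookkeeping hoisted
#' out; `"auto"` picks the fused engine on the virtual clock.
#'
#' @param config An [experiment_config()].
#' @return A `hybrid_experiment` object with elements `trace` (per-sample
#'   tibble: `time`, `phase`, `v_live`, `v_model`, `i_model_to_live`,
#'   `i_live_to_model`), `intervals` (interval-record tibble), `latency`
#'   (a `latency_summary`), `calibration`, `antiphase` (circular burst-phase
#'   summary of the coupled phase) and `log` (character lines, also written
#'   to disk when `config$output_dir` is set).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  fs <- config$fs
  engine <- config$engine
  if (engine == "auto") engine <- if (config$clock == "wall") "loop" else "fused"
  if (config$clock == "wall") engine <- "loop"
  clock <- if (config$clock == "wall") clock_wall() else clock_virtual()
  prep <- virtual_preparation(fs = fs,
                              target_period_s = config$prep_period_s,
                              live_range = config$live_range,
                              noise_sd = config$prep_noise_sd,
                              drift_mv_per_min = config$prep_drift_mv_per_min,
                              soma_tau_s = config$prep_soma_tau_s)

  n_pre <- as.integer(round(config$pre_s * fs))
  n_cpl <- as.integer(round(config$coupled_s * fs))
  n_post <- as.integer(round(config$post_s * fs))
  if (n_pre < fs) stop_bad("pre-control phase must be at least 1 s for calibration")

  scaling <- config$scaling
  env <- new.env()
  env$prep <- prep
  env$coupled <- FALSE
  env$v_live <- config$live_range[1]
  env$v_model <- config$live_range[1]
  env$i_m2l <- 0; env$i_l2m <- 0
  env$m_gate <- 0
  env$dstate <- drift_state(config$drift_tau_s, config$drift_window_s,
                            enabled = config$drift_compensation)
  env$correction <- 0
  w_len <- max(1L, as.integer(round(config$drift_window_s * fs)))
  env$win <- numeric(w_len); env$win_i <- 0L
  env$emit <- NULL
  env$ms <- NULL            # model stream state (set after calibration)
  env$ch <- writer_channel()
  env$blk_n <- 10000L
  env$blk <- matrix(0, 10000L, 4L)
  env$blk_i <- 0L
  env$dt <- 1 / fs

  # ---- the per-interval operations, in the canonical order ----------------
  tasks <- list(
    daq_exchange = function(k) {
      # write last interval's command, read the new sample (command volts
      # carry the model->live current; raw volts carry membrane potential)
      command_v <- -env$i_m2l / scaling$na_per_v
      i_inj <- scaling$na_per_v * command_v
      raw_v <- prep_step(env$prep, i_inj) / scaling$input_factor
      env$v_live <- scaling$input_factor * raw_v
    },
    drift = function(k) {
      if (env$dstate$enabled) {
        i <- env$win_i + 1L
        env$win[i] <- env$v_live
        if (i == length(env$win)) {
          up <- update_drift(env$dstate, env$win)
          env$dstate <- up$state
          env$correction <- up$correction
          env$win_i <- 0L
        } else env$win_i <- i
        env$v_live <- env$v_live - env$correction
      }
    },
    synapses = function(k) {
      if (env$coupled) {
        rng <- env$pre_range
        # slow graded, model -> living (presynaptic: model trace in mV)
        env$m_gate <- graded_slow_step(env$syn_m2l, env$m_gate, env$v_model,
                                       rng, env$dt)
        env$i_m2l <- env$syn_m2l$g * env$m_gate * (env$v_live - env$e_syn_live)
        # fast graded, living -> model (instantaneous activation)
        a <- graded_activation(env$syn_l2m, env$v_live, rng)
        env$i_l2m <- env$syn_l2m$g * a * (env$v_model - env$e_syn_model)
      }
    },
    neuron_model = function(k) {
      if (!is.null(env$emit)) env$v_model <- env$emit(-env$i_l2m)
    },
    enqueue = function(k) {
      i <- env$blk_i + 1L
      env$blk[i, 1L] <- env$v_live
      env$blk[i, 2L] <- env$v_model
      env$blk[i, 3L] <- env$i_m2l
      env$blk[i, 4L] <- env$i_l2m
      if (i == env$blk_n) {
        channel_put(env$ch, env$blk)
        env$blk_i <- 0L
      } else env$blk_i <- i
    })

  drain_samples <- function() {
    if (env$blk_i > 0L) {
      channel_put(env$ch, env$blk[seq_len(env$blk_i), , drop = FALSE])
      env$blk_i <- 0L
    }
    do.call(rbind, channel_drain(env$ch))
  }

  run_phase <- function(n, t0) {
    if (n == 0L) return(list(samples = matrix(0, 0, 4), records = NULL))
    if (engine == "fused") {
      fused_phase(env, config, n, t0)
    } else {
      sched <- loop_schedule(fs, t0 = t0)
      records <- run_loop(sched, tasks, clock, n,
                          record_every = config$record_every)
      list(samples = drain_samples(), records = records)
    }
  }

  log_lines <- c(
    sprintf("hybridclamp experiment | fs %g Hz | phases %g/%g/%g s | seed %d | %s clock (%s engine)",
            fs, config$pre_s, config$coupled_s, config$post_s, config$seed,
            config$clock, engine),
    sprintf("neuron model: %s (%s)", config$model$name, config$model$kind),
    sprintf("  params: %s", paste(sprintf("%s=%g", names(config$model$params),
                                          unlist(config$model$params)),
                                  collapse = ", ")),
    sprintf("synapse model->live: %s g=%g uS", config$syn_model_to_live$type,
            config$syn_model_to_live$g),
    sprintf("synapse live->model: %s g=%g uS", config$syn_live_to_model$type,
            config$syn_live_to_model$g),
    sprintf("acquisition scaling: input x%g, output %g nA/V",
            scaling$input_factor, scaling$na_per_v))

  # ---- pre-control: living neuron only, no coupling -----------------------
  pre <- run_phase(n_pre, 0)

  # ---- calibration on the pre-control window ------------------------------
  live_pre <- pre$samples[, 1L]
  live_range_obs <- range(live_pre)
  live_bursts <- detect_bursts(live_pre, fs = fs, min_gap = 0.1,
                               smooth = 0.005)
  if (nrow(live_bursts) < 3) {
    stop_bad(sprintf("calibration failed: %d burst(s) detected in the %g s pre-control window",
                     nrow(live_bursts), config$pre_s),
             class = "hybridclamp_calibration")
  }
  target_burst <- if (identical(config$target_burst, "auto"))
    mean(live_bursts$duration) else config$target_burst
  cal <- calibrate_model(config$model, fs, target_burst = target_burst,
                         live_range = live_range_obs,
                         integrator = config$integrator)
  env$ms <- new_stream_state(config$model, cal)
  env$emit <- model_streamer(config$model, cal, st = env$ms)
  env$cal <- cal
  env$model <- config$model
  env$pre_range <- live_range_obs
  env$syn_m2l <- config$syn_model_to_live
  env$syn_l2m <- config$syn_live_to_model
  env$e_syn_live <- if (is.na(config$syn_model_to_live$e_syn))
    live_range_obs[1] else config$syn_model_to_live$e_syn
  env$e_syn_model <- if (is.na(config$syn_live_to_model$e_syn))
    live_range_obs[1] else config$syn_live_to_model$e_syn

  log_lines <- c(log_lines,
    sprintf("calibration: live range [%.2f, %.2f] mV | live burst %.3f s (n=%d) | target %.3f s",
            live_range_obs[1], live_range_obs[2], mean(live_bursts$duration),
            nrow(live_bursts), target_burst),
    sprintf("  model range [%.4g, %.4g] -> gain %.4g, offset %.4g",
            cal$native_range[1], cal$native_range[2],
            cal$amplitude$gain, cal$amplitude$offset),
    if (cal$kind == "map")
      sprintf("  interpolation ratio r = %.4g samples per map point",
              cal$time_scale$r)
    else
      sprintf("  model time per interval %.6g (%d substeps)",
              cal$time_scale$dt_per_interval, cal$time_scale$n_substeps),
    sprintf("  synaptic reversals: live %.2f mV, model %.2f mV",
            env$e_syn_live, env$e_syn_model))

  # model runs uncoupled through pre-control; regenerate its column for the
  # whole pre window so both uncoupled traces are shown
  pre_model <- stream_samples(config$model, cal, n_pre)
  pre$samples[, 2L] <- pre_model

  # ---- coupled phase ------------------------------------------------------
  env$coupled <- TRUE
  env$v_model <- pre_model[n_pre]
  cpl <- run_phase(n_cpl, config$pre_s)

  # ---- post-control -------------------------------------------------------
  env$coupled <- FALSE
  env$i_m2l <- 0; env$i_l2m <- 0
  post <- run_phase(n_post, config$pre_s + config$coupled_s)

  samples <- rbind(pre$samples, cpl$samples, post$samples)
  n_tot <- nrow(samples)
  trace <- tibble::tibble(
    time = (seq_len(n_tot) - 1) / fs,
    phase = rep(c("pre", "coupled", "post"), c(n_pre, n_cpl, n_post)),
    v_live = samples[, 1L],
    v_model = samples[, 2L],
    i_model_to_live = samples[, 3L],
    i_live_to_model = samples[, 4L])
  class(trace) <- c("hybrid_trace", class(trace))

  intervals <- dplyr::bind_rows(list(pre$records, cpl$records, post$records))
  lat <- latency_stats(intervals, fail_threshold = 1 / fs)

  antiphase <- tryCatch(
    coupled_antiphase(trace, fs, discard_frac = 0.2),
    error = function(e) NULL)

  log_lines <- c(log_lines,
    sprintf("latency: min %.3g us | max %.3g us | mean %.3g +/- %.3g us | jitter %.3g us | failures %d",
            lat$min * 1e6, lat$max * 1e6, lat$mean * 1e6,
            ifelse(is.na(lat$sd), 0, lat$sd) * 1e6, lat$jitter * 1e6,
            lat$failures),
    if (!is.null(antiphase))
      sprintf("antiphase index (coupled, last 80%%): %.3f (dispersion %.3f, n=%d cycles)",
              antiphase$phase_median, antiphase$dispersion, antiphase$n)
    else "antiphase index: not computable (too few bursts)")

  out <- structure(list(trace = trace, intervals = intervals, latency = lat,
                        calibration = cal, live_bursts = live_bursts,
                        antiphase = antiphase, log = log_lines,
                        config = config),
                   class = "hybrid_experiment")
  if (!is.null(config$output_dir)) write_experiment_outputs(out)
  out
}

# Fused virtual-clock phase: the same operations as the task list, in the
# same order and with identical arithmetic, with all state hoisted into
# locals; the interval records are synthesised afterwards from the same
# anchored-deadline rules run_loop applies (all scripted durations are zero,
# so latency is 0 and sleep is the full period on every interval).
fused_phase <- function(env, config, n, t0) {
  fs <- config$fs
  scaling <- config$scaling
  na_per_v <- scaling$na_per_v
  in_fac <- scaling$input_factor
  dt <- 1 / fs

  prep <- env$prep
  p_model <- prep$model
  p_f <- p_model$derivs; p_ev <- p_model$events
  p_iv <- prep$iv
  p_gain <- prep$amplitude$gain; p_off <- prep$amplitude$offset
  p_h <- prep$dt_int / prep$n_sub; p_nsub <- prep$n_sub
  p_method <- prep$method
  p_state <- unname(prep$state)
  p_t <- prep$t
  p_vf <- prep$v_f
  p_lp <- prep$lp_alpha
  drift_rate <- prep$drift_rate
  noise <- if (prep$noise_sd > 0) stats::rnorm(n, 0, prep$noise_sd) else numeric(n)

  coupled <- env$coupled
  v_live <- env$v_live; v_model <- env$v_model
  i_m2l <- env$i_m2l; i_l2m <- env$i_l2m
  m_gate <- env$m_gate

  drift_on <- env$dstate$enabled
  dstate <- env$dstate; correction <- env$correction
  win <- env$win; win_i <- env$win_i; w_len <- length(win)

  have_model <- !is.null(env$emit)
  if (have_model) {
    m <- env$model; ms <- env$ms; cal <- env$cal
    m_gain <- cal$amplitude$gain; m_off <- cal$amplitude$offset
    m_lo <- cal$amplitude$live_range[1]; m_hi <- cal$amplitude$live_range[2]
    m_iv <- which(names(m$state0) == m$v_var)
    if (m$kind == "map") {
      m_step <- m$map_step
      m_r <- cal$time_scale$r
      m_phase <- ms$phase; m_xprev <- ms$x_prev; m_state <- ms$state
    } else {
      m_f <- m$derivs; m_ev <- m$events
      m_h <- cal$time_scale$dt_per_interval / cal$time_scale$n_substeps
      m_nsub <- cal$time_scale$n_substeps
      m_method <- cal$integrator$method
      m_state <- ms$state
    }
  }
  if (coupled) {
    rng <- env$pre_range
    syn_m2l <- env$syn_m2l; syn_l2m <- env$syn_l2m
    e_live <- env$e_syn_live; e_model <- env$e_syn_model
    g_m2l <- syn_m2l$g; g_l2m <- syn_l2m$g
    k1r <- syn_m2l$k1; k2r <- syn_m2l$k2
    span <- rng[2] - rng[1]
    vth_m2l <- rng[1] + syn_m2l$v_threshold_pct / 100 * span
    s_m2l <- syn_m2l$slope_pct / 100 * span
    vth_l2m <- rng[1] + syn_l2m$v_threshold_pct / 100 * span
    s_l2m <- syn_l2m$slope_pct / 100 * span
  }

  vl <- numeric(n); vm <- numeric(n); im <- numeric(n); il <- numeric(n)
  for (k in seq_len(n)) {
    # daq exchange
    command_v <- -i_m2l / na_per_v
    i_inj <- na_per_v * command_v
    p_input <- i_inj / p_gain
    for (s in seq_len(p_nsub)) {
      kk1 <- p_f(p_state, 0, p_input)
      if (p_method == "euler") {
        p_state <- p_state + p_h * kk1
      } else if (p_method == "heun") {
        kk2 <- p_f(p_state + p_h * kk1, 0, p_input)
        p_state <- p_state + p_h * 0.5 * (kk1 + kk2)
      } else {
        kk2 <- p_f(p_state + p_h / 2 * kk1, 0, p_input)
        kk3 <- p_f(p_state + p_h / 2 * kk2, 0, p_input)
        kk4 <- p_f(p_state + p_h * kk3, 0, p_input)
        p_state <- p_state + p_h / 6 * (kk1 + 2 * kk2 + 2 * kk3 + kk4)
      }
      if (!is.null(p_ev)) p_state <- p_ev(p_state)$state
    }
    v_raw_mv <- p_gain * p_state[[p_iv]] + p_off
    if (is.na(p_vf)) p_vf <- v_raw_mv
    p_vf <- p_vf + p_lp * (v_raw_mv - p_vf)
    p_t <- p_t + dt
    v_mv <- p_vf + drift_rate * p_t + noise[k]
    raw_v <- v_mv / in_fac
    v_live <- in_fac * raw_v
    # drift compensation
    if (drift_on) {
      win_i <- win_i + 1L
      win[win_i] <- v_live
      if (win_i == w_len) {
        up <- update_drift(dstate, win)
        dstate <- up$state
        correction <- up$correction
        win_i <- 0L
      }
      v_live <- v_live - correction
    }
    # synapse models
    if (coupled) {
      a_m2l <- 1 / (1 + exp((vth_m2l - v_model) / s_m2l))
      rate <- k1r * a_m2l + k2r
      m_inf <- k1r * a_m2l / rate
      m_gate <- m_inf + (m_gate - m_inf) * exp(-rate * dt)
      i_m2l <- g_m2l * m_gate * (v_live - e_live)
      a_l2m <- 1 / (1 + exp((vth_l2m - v_live) / s_l2m))
      i_l2m <- g_l2m * a_l2m * (v_model - e_model)
    }
    # neuron model
    if (have_model) {
      m_input <- -i_l2m / m_gain
      if (m$kind == "map") {
        if (m_phase >= 1) {
          m_phase <- m_phase - 1
          m_xprev <- m_state[[m_iv]]
          m_state <- m_step(m_state, m_input)
        }
        v_model <- m_gain * (m_xprev + m_phase * (m_state[[m_iv]] - m_xprev)) + m_off
        if (v_model < m_lo) v_model <- m_lo else if (v_model > m_hi) v_model <- m_hi
        m_phase <- m_phase + 1 / m_r
      } else {
        for (s in seq_len(m_nsub)) {
          kk1 <- m_f(m_state, 0, m_input)
          if (m_method == "euler") {
            m_state <- m_state + m_h * kk1
          } else if (m_method == "heun") {
            kk2 <- m_f(m_state + m_h * kk1, 0, m_input)
            m_state <- m_state + m_h * 0.5 * (kk1 + kk2)
          } else {
            kk2 <- m_f(m_state + m_h / 2 * kk1, 0, m_input)
            kk3 <- m_f(m_state + m_h / 2 * kk2, 0, m_input)
            kk4 <- m_f(m_state + m_h * kk3, 0, m_input)
            m_state <- m_state + m_h / 6 * (kk1 + 2 * kk2 + 2 * kk3 + kk4)
          }
          if (!is.null(m_ev)) m_state <- m_ev(m_state)$state
        }
        v_model <- m_gain * m_state[[m_iv]] + m_off
        if (v_model < m_lo) v_model <- m_lo else if (v_model > m_hi) v_model <- m_hi
      }
    }
    # enqueue
    vl[k] <- v_live; vm[k] <- v_model; im[k] <- i_m2l; il[k] <- i_l2m
  }

  # write state back
  prep$state <- p_state; prep$t <- p_t; prep$v_f <- p_vf
  env$v_live <- v_live; env$v_model <- v_model
  env$i_m2l <- i_m2l; env$i_l2m <- i_l2m
  env$m_gate <- m_gate
  env$dstate <- dstate; env$correction <- correction
  env$win <- win; env$win_i <- win_i
  if (have_model) {
    if (m$kind == "map") {
      ms$phase <- m_phase; ms$x_prev <- m_xprev; ms$state <- m_state
    } else {
      ms$state <- m_state
    }
  }

  idx <- seq(1L, n, by = config$record_every)
  period <- 1 / fs
  records <- tibble::tibble(
    index = idx,
    scheduled = t0 + (idx - 1) * period,
    wake = t0 + (idx - 1) * period,
    latency = 0,
    dur_daq_exchange = 0, dur_drift = 0, dur_synapses = 0,
    dur_neuron_model = 0, dur_enqueue = 0,
    sleep = 1 / fs, overrun = FALSE)
  class(records) <- c("interval_log", class(records))
  list(samples = cbind(vl, vm, im, il), records = records)
}

#' @export
print.hybrid_experiment <- function(x, ...) {
  cat(sprintf("<hybrid_experiment> %s vs virtual preparation at %g Hz\n",
              x$config$model$name, x$config$fs))
  cat(sprintf("  %d samples (%g/%g/%g s), %d interval records\n",
              nrow(x$trace), x$config$pre_s, x$config$coupled_s,
              x$config$post_s, nrow(x$intervals)))
  if (!is.null(x$antiphase)) {
    cat(sprintf("  antiphase index %.3f (dispersion %.3f)\n",
                x$antiphase$phase_median, x$antiphase$dispersion))
  }
  invisible(x)
}

write_experiment_outputs <- function(x) {
  dir <- x$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$trace, file.path(dir, "hybrid_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(x$intervals, file.path(dir, "latency.csv"),
                   row.names = FALSE)
  writeLines(x$log, file.path(dir, "experiment_log.txt"))
  invisible(x)
}

# Burst-phase analysis of the coupled phase after discarding its initial
# transient.
coupled_antiphase <- function(trace, fs, discard_frac = 0.2) {
  cpl <- trace[trace$phase == "coupled", ]
  n0 <- floor(nrow(cpl) * discard_frac)
  cpl <- cpl[(n0 + 1):nrow(cpl), ]
  b_live <- detect_bursts(data.frame(time = cpl$time, v = cpl$v_live),
                          fs = fs, min_gap = 0.1, smooth = 0.005)
  b_model <- detect_bursts(data.frame(time = cpl$time, v = cpl$v_model),
                           fs = fs, min_gap = 0.1, smooth = 0.005)
  antiphase_index(b_live, b_model)
}

#' Circular burst-phase index between two units
#'
#' For every cycle of the reference (living) unit -- burst midpoint to next
#' burst midpoint -- each model burst midpoint falling inside the cycle is
#' assigned a phase in `[0, 1)`.  Exact alternation (each burst centred in
#' the partner's quiescent interval) gives 0.5 regardless of the two duty
#' cycles, which is why midpoints rather than onsets anchor the phase; for
#' point events (zero-duration bursts) the midpoint is the onset.  In-phase
#' activity gives 0.  The summary is circular: the median direction and the
#' circular dispersion `1 - R` (mean resultant length `R`).
#'
#' @param bursts_live,bursts_model Burst tables from [detect_bursts()] (at
#'   least 3 bursts each).
#' @return List with `phase_median`, `dispersion`, `n` (cycles used) and
#'   `phases` (the per-cycle phases).
#' @export
antiphase_index <- function(bursts_live, bursts_model) {
  if (nrow(bursts_live) < 3 || nrow(bursts_model) < 2) {
    stop_bad("need at least 3 reference bursts and 2 partner bursts to estimate phase",
             class = "hybridclamp_phase")
  }
  on_l <- (bursts_live$onset + bursts_live$offset) / 2
  on_m <- (bursts_model$onset + bursts_model$offset) / 2
  phases <- numeric(0)
  for (i in seq_len(length(on_l) - 1)) {
    cyc <- c(on_l[i], on_l[i + 1])
    inside <- on_m[on_m >= cyc[1] & on_m < cyc[2]]
    if (length(inside)) {
      phases <- c(phases, (inside - cyc[1]) / (cyc[2] - cyc[1]))
    }
  }
  if (length(phases) < 2) {
    stop_bad("too few model bursts fall inside live cycles",
             class = "hybridclamp_phase")
  }
  ang <- 2 * pi * phases
  r_vec <- c(mean(cos(ang)), mean(sin(ang)))
  R <- sqrt(sum(r_vec^2))
  med <- circular_median(phases)
  list(phase_median = med, dispersion = 1 - R, n = length(phases),
       phases = phases)
}

# Circular median: the sample point minimising summed circular distance.
circular_median <- function(phases) {
  dist_sum <- vapply(phases, function(p) {
    d <- abs(phases - p)
    sum(pmin(d, 1 - d))
  }, numeric(1))
  phases[which.min(dist_sum)]
}
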