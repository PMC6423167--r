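#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a latency summary
#'
#' @param x A `latency_summary` from [latency_stats()].
#' @param ... Unused.
#' @return `tidy()` gives the histogram as a tibble (one row per bin);
#'   `glance()` a one-row tibble of the summary statistics.
#' @method tidy latency_summary
#' @export
tidy.latency_summary <- function(x, ...) x$histogram

#' @rdname tidy.latency_summary
#' @method glance latency_summary
#' @export
glance.latency_summary <- function(x, ...) {
  tibble::tibble(n = x$n, min = x$min, max = x$max, mean = x$mean,
                 sd = x$sd, jitter = x$jitter, failures = x$failures,
                 fail_threshold = x$fail_threshold)
}

#' Tidy a hybrid experiment
#'
#' @param x A `hybrid_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return `tidy()` returns the per-sample trace tibble; `glance()` a
#'   one-row tibble with the experiment's headline quantities (burst
#'   statistics, antiphase index, latency summary).
#' @method tidy hybrid_experiment
#' @export
tidy.hybrid_experiment <- function(x, ...) x$trace

#' @rdname tidy.hybrid_experiment
#' @method glance hybrid_experiment
#' @export
glance.hybrid_experiment <- function(x, ...) {
  tibble::tibble(
    model = x$config$model$name,
    fs = x$config$fs,
    live_burst_s = mean(x$live_bursts$duration),
    live_period_s = if (nrow(x$live_bursts) > 1)
      mean(diff(x$live_bursts$onset)) else NA_real_,
    antiphase = if (!is.null(x$antiphase)) x$antiphase$phase_median else NA_real_,
    antiphase_dispersion = if (!is.null(x$antiphase)) x$antiphase$dispersion else NA_real_,
    latency_max = x$latency$max,
    latency_failures = x$latency$failures)
}

#' Tidy a calibration
#'
#' @param x A `calibration` from [calibrate_model()].
#' @param ... Unused.
#' @return A one-row tibble of the fitted quantities.
#' @method glance calibration
#' @export
glance.calibration <- function(x, ...) {
  tibble::tibble(
    model = x$model, kind = x$kind, fs = x$fs,
    target_burst_s = x$target_burst,
    gain = x$amplitude$gain, offset = x$amplitude$offset,
    native_burst = x$native_burst, native_period = x$native_period,
    r = x$time_scale$r, dt_per_interval = x$time_scale$dt_per_interval,
    n_substeps = x$time_scale$n_substeps)
}

#' Plot a latency histogram
#'
#' Histogram of wake latencies with a logarithmic count axis (the
#' conventional presentation for real-time latency distributions) and the
#' failure threshold marked.
#'
#' @param object A `latency_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot latency_summary
#' @export
autoplot.latency_summary <- function(object, ...) {
  h <- object$histogram
  h$count_plot <- pmax(h$count, NA)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2 * 1e6,
                                  y = .data$count_plot)) +
    ggplot2::geom_col(width = (h$bin_hi - h$bin_lo) * 1e6,
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$fail_threshold * 1e6,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "latency (µs)", y = "intervals (log scale)",
                  title = sprintf("jitter %.3g µs, %d failure(s)",
                                  object$jitter * 1e6, object$failures))
}

#' Plot a hybrid experiment
#'
#' Stacked membrane-potential and synaptic-current panels over the
#' control-coupled-control protocol, phases shaded.
#'
#' @param object A `hybrid_experiment`.
#' @param every Plot every n-th sample (thinning for long traces).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hybrid_experiment
#' @export
autoplot.hybrid_experiment <- function(object, every = 10L, ...) {
  tr <- object$trace[seq(1, nrow(object$trace), by = every), ]
  long <- tibble::tibble(
    time = rep(tr$time, 4),
    value = c(tr$v_live, tr$v_model, tr$i_model_to_live, tr$i_live_to_model),
    series = rep(c("living (mV)", "model (mV)",
                   "I model→live (nA)", "I live→model (nA)"),
                 each = nrow(tr)))
  long$series <- factor(long$series, levels = unique(long$series))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("hybrid circuit: %s vs virtual preparation",
                                  object$config$model$name))
}

#' @rdname autoplot.hybrid_experiment
#' @param experiment A `hybrid_experiment`.
#' @export
plot_hybrid_trace <- function(experiment, every = 10L) {
  autoplot.hybrid_experiment(experiment, every = every)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
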