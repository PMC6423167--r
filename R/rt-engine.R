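#' Periodic-loop schedule
#'
#' A dynamic-clamp loop runs one iteration per acquisition sample on an
#' absolute, anchored schedule: iteration k is due at `t0 + k/fs`.  Deadlines
#' form a fixed arithmetic sequence and are never re-based after an overrun;
#' recovery happens by shrinking or skipping sleep, not by shifting the
#' schedule.
#'
#' @param fs Sampling frequency (Hz).
#' @param t0 Start instant (s).
#' @return A `loop_schedule` with `fs`, `period` (s) and `t0`.
#' @export
loop_schedule <- function(fs, t0 = 0) {
  assert_scalar_pos(fs)
  structure(list(fs = fs, period = 1 / fs, t0 = t0), class = "loop_schedule")
}

#' @rdname loop_schedule
#' @param schedule A `loop_schedule`.
#' @param duration_s Run length (s).
#' @return The exact number of loop intervals in `duration_s`.
#' @export
schedule_intervals <- function(schedule, duration_s) {
  as.integer(round(duration_s * schedule$fs))
}

#' Clock sources for the loop engine
#'
#' The engine is clock-abstracted: a virtual clock advances simulated time by
#' scripted per-operation durations (making scheduling semantics exactly
#' reproducible and testable), while the wall clock uses best-effort OS
#' timing (soft real-time: statistics are collected, no hard bound holds).
#'
#' @param durations Scripted operation durations for the virtual clock:
#'   a single number (seconds, applied to every operation), a named numeric
#'   vector (per operation name), or a function `(op, k)` returning the
#'   duration of operation `op` at iteration `k`.
#' @return A `clock_source`.
#' @export
clock_virtual <- function(durations = 0) {
  structure(list(kind = "virtual", durations = durations),
            class = "clock_source")
}

#' @rdname clock_virtual
#' @export
clock_wall <- function() {
  structure(list(kind = "wall"), class = "clock_source")
}

virtual_duration <- function(durations, op, k) {
  if (is.function(durations)) return(durations(op, k))
  if (length(names(durations))) {
    d <- durations[[op]]
    if (is.null(d) || is.na(d)) 0 else d
  } else durations[[1L]]
}

#' Run the periodic loop
#'
#' Executes `n_iterations` of the dynamic-clamp interval: wake, then the
#' supplied tasks in order (canonically: DAQ exchange, drift compensation,
#' synapse models, neuron model, enqueue to the writer), then sleep until
#' the next deadline.  If an iteration finishes past its next deadline the
#' following iteration wakes immediately -- sleep is reduced or skipped while
#' the deadlines stay anchored -- so a long model computation is absorbed by
#' eating into subsequent sleep rather than shifting the schedule.
#'
#' @param schedule A [loop_schedule()].
#' @param tasks Named list of functions, called as `task(k)` in list order
#'   each iteration.  Task errors stop the loop cleanly; records for
#'   completed iterations are preserved (with the error attached as the
#'   `error` attribute).
#' @param clock A [clock_virtual()] or [clock_wall()].
#' @param n_iterations Number of intervals to run (>= 1).
#' @param record_every Keep one interval record every this many iterations
#'   (thinning for very long runs; timing semantics are unaffected).
#' @return A tibble of interval records: `index`, `scheduled`, `wake`,
#'   `latency`, one duration column per task (`dur_<name>`), `sleep`, and
#'   `overrun`.
#' @export
run_loop <- function(schedule, tasks, clock = clock_virtual(),
                     n_iterations, record_every = 1L) {
  if (n_iterations < 1) stop_bad("`n_iterations` must be >= 1")
  op_names <- names(tasks)
  if (is.null(op_names) || any(op_names == "")) {
    stop_bad("`tasks` must be a fully named list")
  }
  n_ops <- length(tasks)
  p <- schedule$period
  t0 <- schedule$t0
  virtual <- clock$kind == "virtual"
  durs <- if (virtual) clock$durations else NULL

  n_rec <- ceiling(n_iterations / record_every)
  idx_col <- integer(n_rec); sched_col <- numeric(n_rec)
  wake_col <- numeric(n_rec); sleep_col <- numeric(n_rec)
  over_col <- logical(n_rec)
  dur_cols <- matrix(0, n_rec, n_ops)
  loop_error <- NULL

  finish_prev <- -Inf
  rec <- 0L
  if (!virtual) wall0 <- now_s()
  # scripted durations resolved once when they do not depend on k
  const_durs <- if (virtual && !is.function(durs)) {
    vapply(op_names, function(op) virtual_duration(durs, op, 1L), numeric(1))
  } else NULL
  op_d <- numeric(n_ops)
  # one tryCatch around the whole loop (not per task): a raising task stops
  # the run cleanly with all completed records preserved
  loop_error <- tryCatch({
    for (k in seq_len(n_iterations)) {
      deadline <- t0 + (k - 1) * p
      if (virtual) {
        wake <- if (finish_prev > deadline) finish_prev else deadline
        for (j in seq_len(n_ops)) {
          tasks[[j]](k)
          if (is.null(const_durs)) op_d[j] <- virtual_duration(durs, op_names[j], k)
        }
        if (!is.null(const_durs)) op_d <- const_durs
        finish <- wake + sum(op_d)
        finish_prev <- finish
      } else {
        wake <- wall_wait_until(wall0, deadline)
        t_now <- wake
        for (j in seq_len(n_ops)) {
          tasks[[j]](k)
          t_new <- now_s() - wall0
          op_d[j] <- t_new - t_now
          t_now <- t_new
        }
        finish <- t_now
      }
      next_deadline <- t0 + k * p
      sleep <- next_deadline - finish
      if (sleep < 0) sleep <- 0
      if ((k - 1L) %% record_every == 0L) {
        rec <- rec + 1L
        idx_col[rec] <- k; sched_col[rec] <- deadline; wake_col[rec] <- wake
        dur_cols[rec, ] <- op_d
        sleep_col[rec] <- sleep; over_col[rec] <- finish > next_deadline
      }
    }
    NULL
  }, error = function(e) e)
  keep <- seq_len(rec)
  out <- tibble::tibble(
    index = idx_col[keep], scheduled = sched_col[keep],
    wake = wake_col[keep], latency = wake_col[keep] - sched_col[keep])
  for (j in seq_len(n_ops)) out[[paste0("dur_", op_names[j])]] <- dur_cols[keep, j]
  out$sleep <- sleep_col[keep]
  out$overrun <- over_col[keep]
  class(out) <- c("interval_log", class(out))
  if (!is.null(loop_error)) {
    attr(out, "error") <- conditionMessage(loop_error)
  }
  out
}

now_s <- function() proc.time()[["elapsed"]]

# Best-effort wait for the wall clock; returns the achieved wake time
# (seconds since wall0).
wall_wait_until <- function(wall0, deadline) {
  repeat {
    t <- now_s() - wall0
    if (t >= deadline) return(t)
    remaining <- deadline - t
    if (remaining > 2e-3) Sys.sleep(remaining - 1e-3)
  }
}

#' Latency summary of a loop run
#'
#' Summarises wake latencies of an interval log: min, max, mean, standard
#' deviation, jitter (max minus min), a histogram, and the failure count --
#' the number of latencies exceeding `fail_threshold`, conventionally the
#' loop period (e.g. 50 us at 20 kHz).
#'
#' @param records An interval-log tibble from [run_loop()], or any data frame
#'   with a `latency` column (seconds).
#' @param fail_threshold Real-time failure threshold (s).
#' @param n_bins Histogram bin count.
#' @return A `latency_summary` object; see also [tidy.latency_summary()],
#'   [glance.latency_summary()] and [autoplot.latency_summary()].
#' @export
latency_stats <- function(records, fail_threshold, n_bins = 30) {
  lat <- if (is.data.frame(records)) records$latency else as.numeric(records)
  if (!length(lat)) stop_bad("no latency records")
  lo <- min(lat); hi <- max(lat)
  edges <- if (hi > lo) seq(lo, hi, length.out = n_bins + 1) else
    c(lo - 5e-7, lo + 5e-7)
  counts <- graphics::hist(lat, breaks = edges, plot = FALSE)$counts
  structure(list(
    n = length(lat), min = lo, max = hi, mean = mean(lat),
    sd = stats::sd(lat), jitter = hi - lo,
    failures = sum(lat > fail_threshold), fail_threshold = fail_threshold,
    histogram = tibble::tibble(bin_lo = utils::head(edges, -1),
                               bin_hi = utils::tail(edges, -1),
                               count = counts)),
    class = "latency_summary")
}

#' @export
print.latency_summary <- function(x, ...) {
  us <- function(v) sprintf("%.3f us", v * 1e6)
  cat(sprintf("<latency_summary> n=%d\n", x$n))
  cat(sprintf("  min %s | max %s | mean %s +/- %s | jitter %s\n",
              us(x$min), us(x$max), us(x$mean),
              us(if (is.na(x$sd)) 0 else x$sd), us(x$jitter)))
  cat(sprintf("  failures over %s: %d\n", us(x$fail_threshold), x$failures))
  invisible(x)
}

#' Non-blocking writer channel
#'
#' FIFO message queue decoupling the periodic loop from file output, in the
#' spirit of a writer thread fed through an inter-process queue: `put` has
#' amortised constant cost (a pre-allocated buffer doubled on demand, never
#' scanned), so enqueuing from the loop cannot stall an iteration; `drain`
#' empties the queue in arrival order.
#'
#' @return `writer_channel()` returns a channel object.
#' @export
writer_channel <- function() {
  ch <- new.env(parent = emptyenv())
  ch$buf <- vector("list", 256L)
  ch$head <- 1L   # next slot to drain
  ch$tail <- 0L   # last filled slot
  ch$closed <- FALSE
  class(ch) <- "writer_channel"
  ch
}

#' @rdname writer_channel
#' @param ch A writer channel.
#' @param x Message (any R object).
#' @export
channel_put <- function(ch, x) {
  if (ch$closed) stop_bad("channel is closed")
  tail <- ch$tail + 1L
  if (tail > length(ch$buf)) {
    ch$buf <- c(ch$buf, vector("list", length(ch$buf)))
  }
  ch$buf[[tail]] <- x
  ch$tail <- tail
  invisible(ch)
}

#' @rdname writer_channel
#' @export
channel_drain <- function(ch) {
  if (ch$tail < ch$head) return(list())
  out <- ch$buf[ch$head:ch$tail]
  ch$buf <- vector("list", 256L)
  ch$head <- 1L
  ch$tail <- 0L
  out
}

#' @rdname writer_channel
#' @export
channel_close <- function(ch) {
  ch$closed <- TRUE
  invisible(ch)
}

#' @rdname writer_channel
#' @export
channel_size <- function(ch) ch$tail - ch$head + 1L

#' Square-wave benchmark loop
#'
#' The classic latency benchmark: the loop's only task toggles a binary
#' output each interval, producing a square wave of period `2/fs` whose
#' regularity reflects scheduling quality.  On the virtual clock the wave is
#' exact; on the wall clock the recorded latencies measure the host's
#' soft-real-time performance.
#'
#' @param fs Loop frequency (Hz).
#' @param duration_s Run length (s).
#' @param clock A clock source.
#' @return List with `records` (interval log), `trace` (tibble `time`,
#'   `level`) and `summary` (latency stats at threshold `1/fs`).
#' @export
run_benchmark <- function(fs, duration_s, clock = clock_virtual()) {
  schedule <- loop_schedule(fs)
  n <- schedule_intervals(schedule, duration_s)
  env <- new.env()
  env$level <- integer(n)
  env$bit <- 0L
  tasks <- list(toggle = function(k) {
    env$bit <- 1L - env$bit
    env$level[k] <- env$bit
  })
  records <- run_loop(schedule, tasks, clock, n)
  list(records = records,
       trace = tibble::tibble(time = (seq_len(n) - 1) / fs, level = env$level),
       summary = latency_stats(records, fail_threshold = 1 / fs))
}
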