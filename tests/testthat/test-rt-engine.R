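test_that("schedules expose exact period and interval arithmetic", {
  s20 <- loop_schedule(20000)
  expect_equal(s20$period, 50e-6)
  s10 <- loop_schedule(10000)
  expect_equal(s10$period, 100e-6)
  expect_identical(schedule_intervals(s10, 300), 3000000L)
  expect_identical(schedule_intervals(s20, 1), 20000L)
})

test_that("an under-budget loop has zero latency and full residual sleep", {
  sched <- loop_schedule(10000)   # P = 100 us
  clock <- clock_virtual(durations = c(work = 10e-6))
  rec <- run_loop(sched, list(work = function(k) NULL), clock, 200)
  expect_identical(nrow(rec), 200L)
  expect_true(all(rec$latency == 0))
  expect_true(all(abs(rec$sleep - 90e-6) < 1e-12))
  expect_true(all(!rec$overrun))

  one <- run_loop(sched, list(work = function(k) NULL), clock_virtual(), 1)
  expect_identical(nrow(one), 1L)
  expect_identical(one$latency, 0)
})

test_that("an overrun steals sleep from the next interval, deadlines anchored", {
  sched <- loop_schedule(10000)   # P = 100 us
  n_hit <- 50L
  clock <- clock_virtual(durations = function(op, k) {
    if (op == "neuron_model" && k == n_hit) 140e-6 else 0
  })
  tasks <- list(daq_exchange = function(k) NULL, drift = function(k) NULL,
                synapses = function(k) NULL, neuron_model = function(k) NULL,
                enqueue = function(k) NULL)
  rec <- run_loop(sched, tasks, clock, 100)
  expect_true(rec$overrun[n_hit])
  expect_equal(rec$latency[n_hit + 1L], 40e-6, tolerance = 1e-9)
  expect_equal(rec$latency[n_hit + 2L], 0)
  expect_equal(rec$sleep[n_hit], 0)
  # the absolute schedule is never re-based
  expect_equal(rec$scheduled, (seq_len(100) - 1) * 100e-6, tolerance = 1e-12)
})

test_that("multi-period overruns execute every iteration index immediately", {
  sched <- loop_schedule(10000)
  clock <- clock_virtual(durations = function(op, k) if (k == 10) 350e-6 else 0)
  rec <- run_loop(sched, list(work = function(k) NULL), clock, 20)
  expect_identical(nrow(rec), 20L)
  expect_identical(rec$index, 1:20)
  expect_equal(rec$latency[11], 250e-6, tolerance = 1e-12)
  expect_equal(rec$latency[12], 150e-6, tolerance = 1e-12)
  expect_equal(rec$latency[13], 50e-6, tolerance = 1e-12)
  expect_equal(rec$latency[14], 0)
})

test_that("virtual-clock wake equals max(deadline, previous finish) exactly", {
  set.seed(21)
  durs <- stats::runif(300, 0, 150e-6)
  sched <- loop_schedule(10000)
  clock <- clock_virtual(durations = function(op, k) durs[k])
  rec <- run_loop(sched, list(work = function(k) NULL), clock, 300)
  finish <- rec$wake + rec$dur_work
  expected_wake <- pmax(rec$scheduled, c(-Inf, finish[-300]))
  expect_identical(rec$wake, expected_wake)
  expect_true(all(rec$latency >= 0))
  expect_true(all(rec$dur_work >= 0))
})

test_that("a raising task stops the loop cleanly with records preserved", {
  sched <- loop_schedule(1000)
  tasks <- list(work = function(k) if (k == 6) stop("boom") else NULL)
  rec <- run_loop(sched, tasks, clock_virtual(), 20)
  expect_identical(nrow(rec), 5L)
  expect_match(attr(rec, "error"), "boom")
})

test_that("latency summaries match a brute-force oracle", {
  lat <- c(0, 40e-6, 0)
  s <- latency_stats(data.frame(latency = lat), fail_threshold = 50e-6)
  expect_equal(s$jitter, 40e-6)
  expect_identical(s$failures, 0L)

  z <- latency_stats(data.frame(latency = rep(0, 10)), fail_threshold = 1e-4)
  expect_equal(c(z$min, z$max, z$mean, z$jitter), c(0, 0, 0, 0))

  set.seed(33)
  lat <- stats::rexp(1e5, rate = 2e4)
  s <- latency_stats(data.frame(latency = lat), fail_threshold = 1e-4)
  o <- oracle_latency_stats(lat, 1e-4)
  expect_equal(s$min, o$min)
  expect_equal(s$max, o$max)
  expect_equal(s$mean, o$mean)
  expect_equal(s$sd, o$sd)
  expect_equal(s$jitter, o$jitter)
  expect_identical(s$failures, as.integer(o$failures))
  expect_identical(sum(s$histogram$count), length(lat))

  expect_error(latency_stats(data.frame(latency = numeric(0)), 1e-4), "no latency")
})

test_that("the writer channel is a lossless FIFO with amortised-constant puts", {
  ch <- writer_channel()
  for (i in 1:1000) channel_put(ch, i)
  expect_identical(unlist(channel_drain(ch)), 1:1000)
  expect_identical(channel_drain(ch), list())

  # randomised interleaving against a reference queue
  set.seed(17)
  ch <- writer_channel()
  ref <- list()
  got <- list()
  n_put <- 0L
  for (step in 1:500) {
    if (stats::runif(1) < 0.6) {
      n_put <- n_put + 1L
      channel_put(ch, n_put)
      ref[[length(ref) + 1L]] <- n_put
    } else {
      got <- c(got, channel_drain(ch))
    }
  }
  got <- c(got, channel_drain(ch))
  expect_identical(unlist(got), unlist(ref))

  channel_close(ch)
  expect_error(channel_put(ch, 1), "closed")
  expect_identical(channel_drain(ch), list())
})

test_that("the toggle benchmark produces an exact two-sample square wave", {
  bench <- run_benchmark(20000, 0.05)
  lv <- bench$trace$level
  expect_identical(length(lv), 1000L)
  expect_true(all(rle(lv)$lengths == 1))      # alternates every interval
  expect_equal(2 / 20000, 100e-6)             # square-wave period at 20 kHz
  expect_identical(bench$summary$failures, 0L)
})

test_that("wall-clock mode produces soft statistics without hard bounds", {
  bench <- run_benchmark(200, 0.05, clock = clock_wall())
  expect_identical(nrow(bench$records), 10L)
  expect_true(all(is.finite(bench$records$latency)))
  expect_true(all(bench$records$latency >= 0))
  expect_s3_class(bench$summary, "latency_summary")
})

test_that("latency summaries tidy and plot", {
  s <- latency_stats(data.frame(latency = stats::rexp(500, 2e4)),
                     fail_threshold = 1e-4)
  g <- glance(s)
  expect_identical(nrow(g), 1L)
  expect_named(g, c("n", "min", "max", "mean", "sd", "jitter", "failures",
                    "fail_threshold"))
  expect_s3_class(tidy(s), "tbl_df")
  expect_s3_class(autoplot(s), "ggplot")
})
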