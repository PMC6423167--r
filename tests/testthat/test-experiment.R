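# Short phases keep these runs cheap; the full-length study conditions are
# exercised in the acceptance suite.
short_cfg <- function(model = "rulkov_bursting", ...) {
  experiment_config(model = model, fs = 2000, pre_s = 6, coupled_s = 10,
                    post_s = 2, seed = 42, ...)
}

test_that("the fused and generic-loop engines produce identical experiments", {
  e1 <- run_experiment(short_cfg(engine = "fused"))
  e2 <- run_experiment(short_cfg(engine = "loop"))
  expect_identical(e1$trace$v_live, e2$trace$v_live)
  expect_identical(e1$trace$v_model, e2$trace$v_model)
  expect_identical(e1$trace$i_model_to_live, e2$trace$i_model_to_live)
  expect_identical(e1$trace$i_live_to_model, e2$trace$i_live_to_model)
  expect_equal(e1$intervals$latency, e2$intervals$latency)
  expect_lt(max(abs(e1$intervals$sleep - e2$intervals$sleep)), 1e-9)
})

test_that("identical configurations and seeds give bit-identical traces", {
  e1 <- run_experiment(short_cfg())
  e2 <- run_experiment(short_cfg())
  expect_identical(e1$trace, e2$trace)
})

test_that("control phases carry exactly zero current and exact labels", {
  ex <- run_experiment(short_cfg())
  tr <- ex$trace
  fs <- 2000L
  expect_identical(table(tr$phase)[["pre"]], 6L * fs)
  expect_identical(table(tr$phase)[["coupled"]], 10L * fs)
  expect_identical(table(tr$phase)[["post"]], 2L * fs)
  ctrl <- tr$phase != "coupled"
  expect_true(all(tr$i_model_to_live[ctrl] == 0))
  expect_true(all(tr$i_live_to_model[ctrl] == 0))
  expect_true(any(tr$i_model_to_live[!ctrl] != 0))
  # constant sample spacing
  expect_equal(diff(tr$time[1:100]), rep(1 / fs, 99), tolerance = 1e-12)
})

test_that("interval records follow the canonical operation order", {
  ex <- run_experiment(short_cfg(engine = "loop"))
  dur_cols <- grep("^dur_", names(ex$intervals), value = TRUE)
  expect_identical(dur_cols, c("dur_daq_exchange", "dur_drift", "dur_synapses",
                               "dur_neuron_model", "dur_enqueue"))
  expect_identical(nrow(ex$intervals), nrow(ex$trace))
})

test_that("zero-conductance synapses leave the living rhythm untouched", {
  off <- synapse_graded(g = 0, v_threshold_pct = 15, slope_pct = 1,
                        mode = "slow")
  off_fast <- synapse_graded(g = 0, v_threshold_pct = 50, slope_pct = 5)
  ex <- run_experiment(short_cfg(model = "izhikevich_bursting",
                                 syn_model_to_live = off,
                                 syn_live_to_model = off_fast))
  tr <- ex$trace
  per <- function(ph) {
    b <- detect_bursts(data.frame(time = tr$time[tr$phase == ph],
                                  v = tr$v_live[tr$phase == ph]),
                       fs = 2000, min_gap = 0.2, smooth = 0.005)
    mean(diff(b$onset))
  }
  expect_lt(abs(per("coupled") - per("pre")) / per("pre"), 0.05)
  expect_true(all(tr$i_model_to_live == 0))
})

test_that("aborting on an unusable pre-control window is diagnostic", {
  cfg <- short_cfg()
  cfg$pre_s <- 0.5
  expect_error(run_experiment(cfg), "at least 1 s")
})

test_that("the phase index is circular and duty-robust", {
  pt <- function(onsets) tibble::tibble(onset = onsets, offset = onsets,
                                        duration = 0, v_min = NA, v_max = NA)
  # point events: exact antiphase
  a <- antiphase_index(pt(c(0, 1, 2)), pt(c(0.5, 1.5)))
  expect_equal(a$phase_median, 0.5)
  # coincident onsets: in phase
  b <- antiphase_index(pt(c(0, 1, 2, 3)), pt(c(0, 1, 2)))
  expect_equal(b$phase_median, 0)
  expect_lt(b$dispersion, 1e-12)
  # jittered antiphase fixture
  set.seed(13)
  on_l <- 0:40
  on_m <- 0:39 + 0.5 + stats::runif(40, -0.05, 0.05)
  j <- antiphase_index(pt(on_l), pt(on_m))
  expect_gte(j$phase_median, 0.45)
  expect_lte(j$phase_median, 0.55)
  expect_lt(j$dispersion, 0.1)
  # finite-duration bursts in perfect alternation score 0.5 for unequal duty
  live <- tibble::tibble(onset = 0:10, offset = 0:10 + 0.6,
                         duration = 0.6, v_min = NA, v_max = NA)
  model <- tibble::tibble(onset = 0:9 + 0.7, offset = 0:9 + 0.9,
                          duration = 0.2, v_min = NA, v_max = NA)
  alt <- antiphase_index(live, model)
  expect_equal(alt$phase_median, 0.5, tolerance = 1e-9)

  expect_error(antiphase_index(pt(c(0, 1)), pt(c(0.5, 1.5, 2.5))),
               class = "hybridclamp_phase")
})

test_that("free runs deliver calibrated traces with tidy columns", {
  tr <- free_run("rulkov_bursting", 6, fs = 2000, target_burst = 0.5,
                 live_range = c(-60, -25))
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c("time", "v"))
  b <- detect_bursts(tr, min_gap = 0.2)
  expect_equal(steady_burst_duration(b), 0.5, tolerance = 0.05)
})

test_that("experiments write trace, latency and log artefacts", {
  dir <- withr::local_tempdir()
  cfg <- short_cfg(output_dir = dir, record_every = 10L)
  ex <- run_experiment(cfg)
  expect_true(file.exists(file.path(dir, "hybrid_trace.csv")))
  expect_true(file.exists(file.path(dir, "latency.csv")))
  log <- readLines(file.path(dir, "experiment_log.txt"))
  expect_true(any(grepl("calibration", log)))
  expect_true(any(grepl("latency", log)))
  expect_true(any(grepl("rulkov", log)))
  # thinning reduces records, not samples
  expect_identical(nrow(ex$intervals), nrow(ex$trace) %/% 10L)
  expect_identical(nrow(ex$trace), 36000L)
})

test_that("experiment results expose broom-style summaries and plots", {
  ex <- run_experiment(short_cfg())
  g <- glance(ex)
  expect_identical(nrow(g), 1L)
  expect_true(is.finite(g$live_burst_s))
  expect_s3_class(tidy(ex), "tbl_df")
  expect_s3_class(autoplot(ex, every = 50), "ggplot")
  expect_s3_class(glance(ex$calibration), "tbl_df")
})
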