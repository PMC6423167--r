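test_that("electrical synapse current is ohmic and antisymmetric", {
  syn <- synapse_electrical(g = 0.2)
  expect_equal(electrical_current(syn, -40, -60), 4)   # uS * mV -> nA
  expect_equal(electrical_current(syn, -55, -55), 0)
  expect_equal(electrical_current(synapse_electrical(0), 30, -80), 0)

  set.seed(42)
  for (k in 1:50) {
    v <- stats::runif(2, -90, 40)
    expect_identical(electrical_current(syn, v[1], v[2]),
                     -electrical_current(syn, v[2], v[1]))
  }
  expect_error(synapse_electrical(-1), "g")
})

test_that("graded activation is a range-referenced sigmoid", {
  syn <- synapse_graded(g = 0.2, v_threshold_pct = 15, slope_pct = 1,
                        mode = "slow")
  rng <- c(-60, -25)
  v_th <- -60 + 0.15 * 35
  expect_equal(graded_activation(syn, v_th, rng), 0.5)

  # monotone non-decreasing
  vs <- seq(-70, -10, 0.5)
  a <- graded_activation(syn, vs, rng)
  expect_true(all(diff(a) >= 0))

  # >= 10 slopes below threshold the activation is negligible (sigmoid
  # oracle: 1/(1+exp(10)) < 1e-4)
  s_abs <- 0.01 * 35
  expect_lt(graded_activation(syn, v_th - 10 * s_abs, rng), 1e-4)
  expect_lt(1 / (1 + exp(10)), 1e-4)

  fast <- synapse_graded(g = 0.8, v_threshold_pct = 50, slope_pct = 5)
  expect_equal(graded_activation(fast, -42.5, rng), 0.5)

  expect_error(graded_activation(syn, -40, c(-50, -50)), "degenerate")
})

test_that("slow graded kinetics converge to the closed-form fixed point", {
  syn <- synapse_graded(g = 0.2, v_threshold_pct = 15, slope_pct = 1,
                        k1 = 14, k2 = 4, mode = "slow")
  rng <- c(0, 1)
  # activation pinned at 1 (far above threshold)
  m <- 0
  for (k in 1:4000) m <- graded_slow_step(syn, m, 10, rng, 1e-3)
  expect_equal(m, 14 / 18, tolerance = 1e-6)

  # zero activation decays monotonically toward 0
  m <- 0.9; prev <- m
  for (k in 1:100) {
    m <- graded_slow_step(syn, m, -10, rng, 1e-3)
    expect_lt(m, prev)
    prev <- m
  }

  # equilibrium persistence at arbitrary constant activation
  v <- 0.4
  a <- graded_activation(syn, v, rng)
  m_star <- oracle_graded_fixed_point(14, 4, a)
  m <- graded_slow_step(syn, m_star, v, rng, 1e-4)
  expect_equal(m, m_star, tolerance = 1e-9)
})

test_that("random-rate slow synapses all reach k1*a/(k1*a + k2)", {
  set.seed(7)
  for (k in 1:100) {
    k1 <- stats::runif(1, 0.5, 30)
    k2 <- stats::runif(1, 0.5, 30)
    a_target <- stats::runif(1, 0.05, 0.95)
    syn <- synapse_graded(g = 1, v_threshold_pct = 50, slope_pct = 5,
                          k1 = k1, k2 = k2, mode = "slow")
    rng <- c(0, 100)
    # choose the presynaptic voltage realising the target activation
    v_pre <- 50 + 5 * log(a_target / (1 - a_target))
    a <- graded_activation(syn, v_pre, rng)
    m <- 0.5
    for (i in 1:3000) m <- graded_slow_step(syn, m, v_pre, rng, 2e-3)
    expect_equal(m, oracle_graded_fixed_point(k1, k2, a), tolerance = 1e-6)
  }
})

test_that("graded current follows g * gate * (v_post - E_syn)", {
  syn <- synapse_graded(g = 0.8, v_threshold_pct = 50, slope_pct = 5,
                        e_syn = -70)
  expect_equal(graded_current(syn, 0, -40), 0)
  expect_equal(graded_current(syn, 0.7, -70), 0)       # at reversal
  expect_equal(graded_current(syn, 1, -60), 8)         # 0.8 uS * 10 mV
  expect_error(graded_current(syn, 1.4, -40), "gate")
})

test_that("chemical synapse follows transmitter-pulse kinetics", {
  syn <- synapse_chemical(g = 0.2, e_syn = -70, alpha = 0.94, beta = 0.18,
                          t_max = 1, pulse_duration = 1)
  # no spikes: closed-form exponential decay of the open fraction
  s <- 0.6
  dt <- 0.05
  for (k in 1:100) s <- chemical_step(syn, s, numeric(0), (k - 1) * dt,
                                      -60, dt)$s_open
  expect_equal(s, 0.6 * exp(-0.18 * 5), tolerance = 1e-9)

  # a long transmitter pulse saturates at alpha*T/(alpha*T + beta)
  s <- 0
  for (k in 1:6000) {
    s <- chemical_step(syn, s, k * dt, t_now = (k - 1) * dt, v_post = -60,
                       dt = dt)$s_open  # a fresh spike every step: always in pulse
  }
  expect_equal(s, 0.94 / (0.94 + 0.18), tolerance = 1e-6)

  # nothing from nothing
  out <- chemical_step(syn, 0, numeric(0), 0, -20, dt)
  expect_identical(out$current, 0)

  expect_error(chemical_step(syn, 0.1, c(3, 1, 2), 5, -60, dt), "sorted")
})

test_that("gate variables remain in [0,1] under random stepping", {
  set.seed(11)
  syn <- synapse_graded(g = 1, v_threshold_pct = 30, slope_pct = 3,
                        k1 = 14, k2 = 4, mode = "slow")
  chem <- synapse_chemical(g = 1, e_syn = -70)
  m <- 0.5; s <- 0.5
  rng <- c(-80, -20)
  for (k in 1:10000) {
    m <- graded_slow_step(syn, m, stats::runif(1, -120, 20), rng,
                          stats::runif(1, 1e-5, 0.5))
    s <- chemical_step(chem, s, if (k %% 3) numeric(0) else k, k, -50,
                       stats::runif(1, 1e-3, 10))$s_open
    expect_true(m >= 0 && m <= 1)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("spike detection applies threshold crossing with refractory hold", {
  t <- seq(0, 1, by = 1e-3)
  v <- -60 + 40 * (sin(2 * pi * 10 * t) > 0.95)   # brief pulses at 10 Hz
  sp <- detect_spikes(data.frame(time = t, v = v), threshold = -30,
                      refractory = 0.05)
  expect_equal(nrow(sp), 10)
  sp2 <- detect_spikes(data.frame(time = t, v = v), threshold = -30,
                       refractory = 0.3)
  expect_lt(nrow(sp2), 10)
})
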