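test_that("rulkov map honours its fixed point and slow-rate limits", {
  m <- neuron_rulkov(alpha = 4, sigma = 0, mu = 0.001)
  # (x, y) = (-1, -3) is a fixed point: 4/(1-(-1)) - 3 = -1 and x + 1 = 0
  st <- c(x = -1, x_prev = -1, y = -3)
  out <- rulkov_step(m$params, st, input = 0)
  expect_equal(out[["x"]], -1)
  expect_equal(out[["y"]], -3)

  # mu = 0 freezes the slow variable under any iteration
  m0 <- neuron_rulkov(alpha = 4.5, sigma = 0.3, mu = 0)
  st <- m0$state0
  for (k in 1:500) st <- rulkov_step(m0$params, st, input = 0)
  expect_identical(st[["y"]], m0$state0[["y"]])

  expect_error(rulkov_step(m$params, c(x = NaN, x_prev = 0, y = 0)),
               class = "hybridclamp_nonfinite")
})

test_that("rulkov trajectory is bit-identical to a literal map transcription", {
  m <- neuron_rulkov()  # bursting defaults
  n <- 1e5
  ref <- oracle_rulkov(m$params$alpha, m$params$sigma, m$params$mu,
                       m$state0[["x"]], m$state0[["x_prev"]],
                       m$state0[["y"]], n)
  st <- m$state0
  got <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    st <- rulkov_step(m$params, st)
    got[k, ] <- c(st[["x"]], st[["y"]])
  }
  expect_identical(got, ref)
})

test_that("izhikevich derivatives vanish at the quadratic nullcline roots", {
  m <- neuron_izhikevich(b = 0.2, I = 0)
  # with u = b v the voltage equation is 0.04 v^2 + (5 - b) v + 140 = 0;
  # the quadratic-root oracle gives v = -50 and v = -70 for b = 0.2
  roots <- sort(Re(polyroot(c(140, 5 - 0.2, 0.04))))
  expect_equal(roots, c(-70, -50), tolerance = 1e-10)
  for (v in roots) {
    d <- ode_derivs(m, c(v, 0.2 * v))
    expect_equal(d[1], 0, tolerance = 1e-9)
  }
})

test_that("hindmarsh-rose derivatives vanish at the equilibrium root", {
  skip_if_not_installed("pracma")
  m <- neuron_hindmarsh_rose(b = 3, I = 3, r = 0.006, s = 4, x_rest = -1.6)
  f <- function(s) ode_derivs(m, s)
  root <- pracma::fsolve(f, c(-1.3, -7, 1.2))$x
  expect_lt(max(abs(ode_derivs(m, root))), 1e-9)
})

test_that("conductance gating derivatives are zero at steady state", {
  gh <- neuron_ghigliazza_holmes()
  v <- -35
  p <- gh$params
  w_inf <- 1 / (1 + exp(-(v - p$vw_half) / p$vw_slope))
  c_inf <- 1 / (1 + exp(-(v - p$vc_half) / p$vc_slope))
  d <- ode_derivs(gh, c(v, w_inf, c_inf))
  expect_equal(d[2], 0)
  expect_equal(d[3], 0)

  wang <- neuron_wang()
  q_inf <- 1 / (1 + exp(-(v - wang$params$vq_half) / wang$params$vq_slope))
  d <- ode_derivs(wang, c(v, 0.1, 0.2, 0.3, q_inf))
  expect_equal(d[5], 0)
})

test_that("ode_derivs rejects dimension mismatches and non-ODE models", {
  m <- neuron_izhikevich()
  expect_error(ode_derivs(m, c(1, 2, 3)), "length")
  expect_error(ode_derivs(neuron_rulkov(), c(1, 2, 3)), "ode")
})

test_that("discrete reset events fire inclusively at the peak", {
  m <- neuron_izhikevich(c = -50, d = 2, peak = 30)
  fired <- apply_discrete_events(m, c(35, -10))
  expect_true(fired$fired)
  expect_equal(unname(fired$state), c(-50, -8))

  quiet <- apply_discrete_events(m, c(-60, -12))
  expect_false(quiet$fired)
  expect_equal(unname(quiet$state), c(-60, -12))

  edge <- apply_discrete_events(m, c(30, 0))
  expect_true(edge$fired)

  # models without reset rules pass state through
  hr <- neuron_hindmarsh_rose()
  expect_false(apply_discrete_events(hr, hr$state0)$fired)
})

test_that("every stock preset free-runs in a regular bursting regime", {
  for (nm in stock_models) {
    m <- neuron_preset(nm)
    nr <- hybridclamp:::native_run(m)
    expect_gte(nrow(nr$bursts), 8)
    cv <- stats::sd(nr$bursts$duration) / mean(nr$bursts$duration)
    expect_lt(cv, 0.15)
  }
})

test_that("gating variables stay in [0,1] through long conductance runs", {
  for (ctor in list(neuron_ghigliazza_holmes, neuron_wang)) {
    m <- ctor()
    # largest step the selection rule accepts for a generous interval budget
    sel <- select_step(integrator_spec("rk4"), m, m$native_dt * 8)
    st <- unname(m$state0)
    worst_lo <- 0; worst_hi <- 1
    for (k in 1:20000) {
      st <- hybridclamp:::step_model(m, st, m$native_dt * 8, sel$n_substeps,
                                     "rk4")
      g <- st[m$gating_idx]
      worst_lo <- min(worst_lo, g); worst_hi <- max(worst_hi, g)
    }
    expect_gte(worst_lo, -1e-9)
    expect_lte(worst_hi, 1 + 1e-9)
  }
})

test_that("tabulated nonlinearities track the direct functions", {
  # tabulated vs direct conductance models agree over a burst
  gh_direct <- neuron_ghigliazza_holmes()
  gh_tab <- neuron_ghigliazza_holmes(use_tables = TRUE)
  st_d <- unname(gh_direct$state0); st_t <- unname(gh_tab$state0)
  worst <- 0
  for (k in 1:30000) {  # ~3 s of model time, one burst cycle
    st_d <- hybridclamp:::step_model(gh_direct, st_d, 0.1, 1L, "rk4")
    st_t <- hybridclamp:::step_model(gh_tab, st_t, 0.1, 1L, "rk4")
    worst <- max(worst, abs(st_d[1] - st_t[1]))
  }
  expect_lt(worst, 0.5)  # mV over a full burst, dominated by spike timing
})
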