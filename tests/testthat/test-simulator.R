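test_that("shifted Hill function has the correct limits, midpoint and bounds", {
  expect_equal(shifted_hill(0, 10, 4, 9), 1)
  expect_equal(shifted_hill(1e9, 10, 4, 9), 9, tolerance = 1e-6)
  expect_equal(shifted_hill(10, 10, 4, 9), 5)        # (1 + lambda) / 2
  expect_equal(shifted_hill(10, 10, 2, 0.2), 0.6)
  x <- seq(0, 100, by = 0.5)
  h_act <- shifted_hill(x, 20, 3, 50)
  expect_true(all(h_act >= 1 & h_act <= 50))
  expect_true(all(diff(h_act) >= 0))
  h_inh <- shifted_hill(x, 20, 3, 0.02)
  expect_true(all(h_inh <= 1 & h_inh >= 0.02))
  expect_true(all(shifted_hill(x, 20, 3, 1) == 1))   # inert edge
  expect_error(shifted_hill(1, 0, 2, 5), "positive")
  expect_error(shifted_hill(1, 1, 0, 5), "Hill")
})

test_that("rate equations vanish at fixed points and reduce to production at zero", {
  f <- unregulated_toggle_model()
  x_star <- f$params$G / f$params$K
  expect_equal(derivative(as.vector(x_star), f$params, f$circuit),
               c(0, 0), tolerance = 1e-12)
  expect_equal(derivative(c(0, 0), f$params, f$circuit),
               unname(f$params$G))

  # a state found by relaxation is a root of the rate equations as found
  # by an independent nonlinear solver
  ts <- fixture_circuit("TS")
  m <- sample_model(ts, default_ranges(ts), seed = 7)
  x0 <- random_initial_conditions(ts, 1, seed = 3)
  term <- simulate_model(m, ts, sim_config(T = 150), x0 = as.vector(x0))
  xT <- term$expression[1, ]
  expect_lt(sqrt(sum(derivative(xT, m, ts)^2)), 1e-4)
  root <- pracma::fsolve(function(x) derivative(x, m, ts), xT * 1.05)$x
  expect_equal(unname(xT), unname(root), tolerance = 1e-3)
})

test_that("zero-noise stochastic stepping is exactly forward Euler", {
  ts <- fixture_circuit("TS")
  m <- sample_model(ts, default_ranges(ts), seed = 2)
  x <- c(5, 80)
  expect_identical(step_em(x, m, ts, dt = 0.05, D = 0),
                   pmax(x + derivative(x, m, ts) * 0.05, 0))
  # whole trajectories: SDE at D = 0 bitwise-equals the Euler ODE path
  cfg <- sim_config(T = 20, record_times = 1:20)
  tr1 <- simulate_model(m, ts, cfg, x0 = c(1, 1))
  x <- c(1, 1)
  manual <- matrix(NA_real_, 20, 2)
  for (s in seq_len(round(20 / cfg$dt))) {
    x <- pmax(x + derivative(x, m, ts) * cfg$dt, 0)
    if (s %% 20 == 0) manual[s / 20, ] <- x
  }
  expect_identical(unname(tr1$expression), manual)
})

test_that("the C++ ensemble integrator matches the R single-model path", {
  ts <- fixture_circuit("TS_SA2")
  r <- default_ranges(ts)
  ens <- sample_ensemble(ts, r, n_models = 3, seed = 11)
  x0 <- random_initial_conditions(ts, 3, seed = 4)
  term <- simulate_ensemble(ens, x0 = x0, D = 0, T = 30)
  for (i in 1:3) {
    tr <- simulate_model(ensemble_model(ens, i), ts, sim_config(T = 30),
                         x0 = x0[i, ])
    expect_equal(unname(term[i, ]), unname(tr$expression[1, ]),
                 tolerance = 1e-12)
  }
})

test_that("noisy trajectories stay nonnegative and are seed-reproducible", {
  ts <- fixture_circuit("TS")
  m <- sample_model(ts, default_ranges(ts), seed = 5)
  cfg <- sim_config(D = 40, T = 20, record_times = seq(0.5, 20, by = 0.5),
                    seed = 31)
  tr1 <- simulate_model(m, ts, cfg)
  tr2 <- simulate_model(m, ts, cfg)
  expect_identical(tr1$expression, tr2$expression)
  expect_true(all(tr1$expression >= 0))
  expect_equal(nrow(tr1$expression), 40)
  # x = 0 with no production stays at 0 under the clamp... and with noise
  m0 <- m; m0$G[] <- 0
  tr0 <- simulate_model(m0, ts, sim_config(D = 5, T = 5, seed = 1),
                        x0 = c(0, 0))
  expect_true(all(tr0$expression >= 0))
})

test_that("stationary variance of an unregulated gene matches the OU closed form", {
  f <- unregulated_toggle_model()
  D <- 2
  cfg <- sim_config(dt = 0.01, T = 2000, D = D,
                    record_times = seq(100, 2000, by = 1), seed = 5)
  tr <- simulate_model(f$params, f$circuit, cfg,
                       x0 = as.vector(f$params$G / f$params$K))
  v <- apply(tr$expression, 2, stats::var)
  expect_equal(unname(v), unname(D^2 / (2 * f$params$K)),
               tolerance = 0.15)
})

test_that("halving dt changes converged zero-noise terminal states by < 1e-3 relative", {
  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 50, seed = 21)
  x0 <- random_initial_conditions(ts, 50, seed = 22)
  a <- simulate_ensemble(ens, x0 = x0, D = 0, T = 100, dt = 0.05)
  b <- simulate_ensemble(ens, x0 = x0, D = 0, T = 100, dt = 0.025)
  expect_lt(max(abs(a - b) / pmax(a, 1)), 1e-3)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(T = 0.01), "T must")
  expect_error(sim_config(D = -1), "nonnegative")
  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 2, seed = 1)
  expect_error(simulate_ensemble(ens, x0 = matrix(1, 3, 2)), "x0 rows")
})
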