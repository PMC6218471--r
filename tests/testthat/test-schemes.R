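test_that("noise ladders are strictly decreasing and end exactly at zero", {
  nl <- noise_ladder(50, 30, 5)
  expect_length(nl$levels, 30)
  expect_true(all(diff(nl$levels) < 0))
  expect_identical(nl$levels[30], 0)
  expect_error(noise_ladder(0), "positive")
  expect_error(noise_ladder(50, 1), "two levels")
  expect_error(noise_ladder(50, 10, 0), "tau")
})

test_that("SIC traps at low noise, explores both wells at high noise, and is a point at D = 0", {
  a <- double_well("a")
  lv <- dw_noise_levels(a)
  lo <- run_sic(a, D = lv[["low"]], T_total = 500, record_interval = 0.5,
                seed = 5)
  occ <- dw_occupancy(lo, a)$fractions
  expect_true(any(occ == 1))                 # every record in one well

  hi <- run_sic(a, D = lv[["high"]], T_total = 2000,
                record_interval = 0.5, seed = 5)
  occ_hi <- dw_occupancy(hi, a)$fractions
  expect_true(all(occ_hi > 0.35))            # both wells visited often

  det <- run_sic(a, D = 0, T_total = 50, record_interval = 1, seed = 5,
                 burn_in = 50)
  expect_lt(stats::sd(det$expression[, 1]), 1e-6)
})

test_that("MIC occupancy tracks basin shares for the unequal-basin potential", {
  cc <- double_well("c")
  lv <- dw_noise_levels(cc)
  mic <- run_mic(cc, D = lv[["low"]], T = 50, seed = 6, n = 2000)
  occ <- dw_occupancy(mic, cc)
  expected_left <- (cc$barrier - cc$box[1]) / diff(cc$box)
  expect_equal(occ$fractions[1], expected_left, tolerance = 0.04)
})

test_that("SA concentrates the ensemble in the deeper well", {
  for (v in c("b", "d")) {
    dw <- double_well(v)
    sa <- run_sa(dw, seed = 7, n = 1000)
    final <- sa[[length(sa)]]
    expect_identical(final$D[1], 0)
    occ <- dw_occupancy(final, dw)
    deeper <- which.max(dw$depths)
    expect_gte(occ$fractions[deeper], 0.95)
  }
})

test_that("SA matches MIC on the symmetric potential at every ladder level", {
  a <- double_well("a")
  sa <- run_sa(a, seed = 8, n = 2000)
  for (res in sa) {
    occ <- dw_occupancy(res, a)
    expect_equal(occ$fractions[1], 0.5, tolerance = 0.06)
  }
})

test_that("all three schemes agree at high noise (pairwise BD < 0.05)", {
  a <- double_well("a")
  lv <- dw_noise_levels(a)
  sic <- run_sic(a, D = lv[["high"]], T_total = 2000,
                 record_interval = 0.5, seed = 5)
  mic <- run_mic(a, D = lv[["high"]], T = 50, seed = 9, n = 2000)
  sa <- run_sa(a, seed = 8, n = 2000)
  sa_lv <- vapply(sa, function(r) r$D[1], 0)
  sa_hi <- sa[[which.min(abs(sa_lv - lv[["high"]]))]]
  pairs <- list(list(sic, mic), list(sic, sa_hi), list(mic, sa_hi))
  for (p in pairs)
    expect_lt(bd_expression(p[[1]]$expression, p[[2]]$expression,
                            n_bins = 60, log2_transform = FALSE), 0.05)
})

test_that("a one-level ladder at D = 0 reproduces zero-noise MIC exactly", {
  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 100, seed = 3)
  mic <- run_mic(ens, D = 0, T = 5, seed = 11)
  ladder <- structure(list(levels = 0, tau = 5), class = "noise_ladder")
  sa <- run_sa(ens, ladder, seed = 11)
  expect_equal(sa[[1]]$expression, mic$expression)
})

test_that("scheme runs are bitwise reproducible from (seed, config)", {
  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 200, seed = 3)
  m1 <- run_mic(ens, D = 10, T = 10, seed = 4)
  m2 <- run_mic(ens, D = 10, T = 10, seed = 4)
  expect_identical(m1$expression, m2$expression)
  s1 <- run_sa(ens, noise_ladder(20, 5, 2), seed = 6)
  s2 <- run_sa(ens, noise_ladder(20, 5, 2), seed = 6)
  expect_identical(s1[[5]]$expression, s2[[5]]$expression)
  r1 <- run_noise_randomized_mic(ens, D_max = 50, T = 10, seed = 8)
  r2 <- run_noise_randomized_mic(ens, D_max = 50, T = 10, seed = 8)
  expect_identical(r1$expression, r2$expression)
  expect_identical(r1$D, r2$D)
})

test_that("noise-randomized MIC annotates records with their own noise level", {
  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 300, seed = 3)
  run <- run_noise_randomized_mic(ens, D_max = 50, T = 10, seed = 8)
  expect_length(run$D, 300)
  expect_true(all(run$D >= 0 & run$D < 50))
  expect_gt(stats::sd(run$D), 5)
  # the D_max -> 0 limit is deterministic MIC: all noise levels zero and
  # every terminal is a fixed point
  run0 <- run_noise_randomized_mic(ens, D_max = 0, T = 60, seed = 8)
  expect_true(all(run0$D == 0))
  rate <- stochcirc:::derivative_matrix(run0$expression, ens, ts)
  resid <- sqrt(rowSums(rate^2)) / pmax(sqrt(rowSums(run0$expression^2)), 1)
  expect_lt(stats::median(resid), 1e-6)
})

test_that("ensemble results survive a disk round trip", {
  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 50, seed = 3)
  run <- run_mic(ens, D = 2, T = 5, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_ensemble_result(run, path)
  back <- read_ensemble_result(path)
  expect_equal(back$expression, run$expression, tolerance = 1e-6)
  expect_identical(back$model_id, run$model_id)
  expect_equal(back$D, run$D)
})
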