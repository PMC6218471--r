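test_that("Bhattacharyya distance satisfies its axioms and hand-computed values", {
  expect_identical(bhattacharyya_distance(c(.5, .5), c(.5, .5)), 0)
  expect_equal(bhattacharyya_distance(c(.5, .5), c(.9, .1)),
               -log(sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)
  expect_equal(bhattacharyya_distance(c(.5, .5), c(.9, .1)), 0.1115718,
               tolerance = 1e-6)
  # disjoint supports hit the documented ceiling
  expect_identical(bhattacharyya_distance(c(1, 0), c(0, 1)), 20)
  expect_identical(bhattacharyya_distance(c(1, 0), c(0, 1), cap = 7), 7)

  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:30, 1)
    p <- stats::runif(k); p <- p / sum(p)
    q <- stats::runif(k); q <- q / sum(q)
    bd_pq <- bhattacharyya_distance(p, q)
    expect_gte(bd_pq, 0)
    expect_equal(bd_pq, bhattacharyya_distance(q, p))
    expect_equal(bhattacharyya_distance(p, p), 0, tolerance = 1e-12)
  }
  expect_error(bhattacharyya_distance(c(.5, .5), c(1, 0, 0)),
               "different binnings")
  expect_error(bhattacharyya_distance(c(.7, .7), c(.5, .5)), "sum to 1")
  expect_error(bhattacharyya_distance(c(1.5, -0.5), c(.5, .5)),
               "nonnegative")
})

test_that("normalization is centered on its reference and reusable across slices", {
  set.seed(1)
  m <- matrix(stats::rexp(600, 0.05), 200, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  nm <- normalize_expression(m)
  expect_equal(unname(colMeans(nm$matrix)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(nm$matrix, 2, stats::sd)), c(1, 1, 1),
               tolerance = 1e-12)
  # stored transform re-applies deterministically to new data
  m2 <- m * 2
  z1 <- normalize_expression(m2, transform = nm$transform)
  z2 <- normalize_expression(m2, transform = nm$transform)
  expect_identical(z1$matrix, z2$matrix)
  expect_false(isTRUE(all.equal(colMeans(z1$matrix), c(A = 0, B = 0,
                                                       C = 0))))
  # constant gene: warned, mapped to zeros
  m3 <- cbind(A = rep(4, 100), B = stats::rexp(100))
  expect_warning(n3 <- normalize_expression(m3), "zero-variance")
  expect_true(all(n3$matrix[, "A"] == 0))
})

test_that("state counting resolves separated clusters and degenerate data", {
  set.seed(3)
  two <- rbind(matrix(stats::rnorm(400, -3, .4), ncol = 2),
               matrix(stats::rnorm(400, 3, .4), ncol = 2))
  sc2 <- count_states(two)
  expect_identical(sc2$k, 2L)
  expect_equal(sc2$occupancy$fractions, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(sc2$occupancy$fractions), 1, tolerance = 1e-12)

  one <- matrix(stats::rnorm(600), ncol = 2)
  expect_identical(count_states(one)$k, 1L)

  point <- matrix(1.5, 100, 2)
  expect_identical(count_states(point)$k, 1L)

  expect_error(count_states(matrix(0, 10, 2)), "too few records")
})

test_that("global bifurcation bins by the control parameter and flags empty bins", {
  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 800, seed = 3)
  run <- run_mic(ens, D = 5, T = 20, seed = 4)   # constant D
  prof <- global_bifurcation(run, n_bins = 4, control_range = c(0, 20),
                             min_records = 50)
  expect_equal(sum(prof$n), 800)      # all records fall into one bin
  full <- which(prof$n > 0)
  expect_length(full, 1)
  expect_true(all(is.na(prof$k[-full])))  # empty bins flagged, kept
  expect_false(is.na(prof$k[full]))
})

test_that("PCA embedding conserves variance, fixes signs, and separates toggle states", {
  set.seed(6)
  m <- matrix(stats::rnorm(300), 100, 3)
  emb <- pca_embed(m, n_components = 3)
  expect_equal(sum(apply(emb$scores, 2, stats::var)),
               sum(apply(scale(m, scale = FALSE), 2, stats::var)),
               tolerance = 1e-12)
  for (j in 1:3)
    expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)

  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 2000, seed = 5)
  run <- run_mic(ens, D = 0, T = 50, seed = 6)
  z <- normalize_expression(run)
  emb2 <- pca_embed(z)
  side <- z$matrix[, 1] > z$matrix[, 2]
  gap <- abs(mean(emb2$scores[side, 1]) - mean(emb2$scores[!side, 1]))
  expect_gt(gap, 1)    # PC1 separates the two expression states
  expect_error(pca_embed(matrix(1, 5, 1)), "at least 2 genes")
})

test_that("duplicate records join at height zero in the dendrogram", {
  m <- rbind(c(1, 2), c(1, 2), c(5, 6), c(8, 0))
  hc <- hierarchical_cluster(m, k = 3)
  expect_equal(min(hc$tree$height), 0)
  expect_identical(hc$labels[1], hc$labels[2])
  expect_identical(hc$tree$method, "average")
})

test_that("response curves vanish against their own endpoint and settle monotonically", {
  ts <- fixture_circuit("TS")
  rc <- response_curve(ts, n_models = 1000, D = 0,
                       record_times = c(1, 5, 10, 25, 50), seed = 4)
  expect_identical(rc$BD[5], 0)            # T = 50 snapshot vs itself
  expect_true(all(diff(rc$BD) <= 0))       # relaxation toward the target
  expect_identical(response_time(rc, threshold = 1e9), 1)
  expect_identical(response_time(data.frame(time = 1:3,
                                            BD = c(1, 1, 1)), 0.5), Inf)
})

test_that("noise robustness is zero at D = 0 and non-decreasing on the grid", {
  ts <- fixture_circuit("TS")
  rb <- noise_robustness(ts, n_models = 2000,
                         D_grid = c(0, 0.5, 1, 5, 20), seed = 8)
  expect_identical(rb$curve$BD[1], 0)
  expect_true(all(diff(rb$curve$BD) > -1e-4))
  expect_gt(rb$RD, 0)
  expect_gt(rb$slope, 0)
  expect_error(noise_robustness(ts, n_models = 10, D_grid = c(0, 2)),
               "contain both 0 and 1")
})
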