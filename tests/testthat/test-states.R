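test_that("state enumeration finds the toggle switch's coexisting fixed points", {
  ts <- fixture_circuit("TS")
  ens <- sample_ensemble(ts, n_models = 300, seed = 2)
  en <- enumerate_states(ens, n_ic = 50, seed = 3)
  # rare pathological models converge nowhere and report zero states;
  # every model with converged instances reports at least one
  expect_true(all(en$n_states[en$converged > 0] >= 1))
  expect_lte(max(en$n_states), 3)   # two switched states + co-expression
                                    # is the most a plain toggle admits
  # most random toggle models are monostable (winner-take-all or
  # co-expressing); a minority is genuinely bistable
  expect_gt(mean(en$n_states == 2), 0.03)
  expect_gt(mean(en$n_states == 1), 0.5)
  expect_gt(mean(en$converged), 0.95)
  # occupancy counts account for every converged instance
  m <- which(en$n_states >= 2)[1]
  expect_equal(sum(en$occupancy[[m]]), round(en$converged[m] * 50))
  # every reported state is a fixed point of its model
  p <- ensemble_model(ens, m)
  for (s in seq_len(nrow(en$states[[m]]))) {
    x <- en$states[[m]][s, ]
    expect_lt(sqrt(sum(derivative(x, p, ts)^2)) / max(sqrt(sum(x^2)), 1),
              1e-3)
  }
})

test_that("quadrastable selection returns cleanly labeled four-state models", {
  q <- get_quadrastable_fixture()
  expect_gt(length(q$model_idx), 10)
  for (i in seq_along(q$model_idx)) {
    sm <- q$state_coords[[i]]
    expect_identical(rownames(sm), c("LL", "LH", "HL", "HH"))
    # labels are consistent with the actual expression ordering
    expect_lt(sm["LL", "A"], sm["HL", "A"])
    expect_lt(sm["LL", "B"], sm["LH", "B"])
    expect_lt(sm["LH", "A"], sm["HH", "A"])
    expect_lt(sm["HL", "B"], sm["HH", "B"])
  }
  expect_error(find_quadrastable(sample_ensemble(fixture_circuit("FIVE_TS"),
                                                 n_models = 2, seed = 1)),
               "two-gene")
})

test_that("unit induction is the identity and induction is hysteretic", {
  q <- get_quadrastable_fixture()
  id <- induction_experiment(q, data.frame(A = 1, B = 1), "LL")
  expect_true(all(id$stages[[1]]$labels == "LL"))

  # ramped simultaneous induction from low-low progressively empties LL
  # and ends with the great majority in high-high
  ramp <- induction_experiment(q, data.frame(A = c(1, 1.55, 1.8, 15),
                                             B = c(1, 1.55, 1.8, 15)),
                               "LL")
  ll <- vapply(ramp$stages, function(s) s$fractions[["LL"]], 0)
  expect_true(all(diff(ll) <= 0))
  expect_gt(ramp$stages[[4]]$fractions[["HH"]], 0.5)

  # removing the induction does not send models back to low-low
  rem <- induction_experiment(q, data.frame(A = c(15, 1), B = c(15, 1)),
                              "HH")
  expect_equal(rem$stages[[2]]$fractions[["HH"]], 1)
  expect_equal(rem$stages[[2]]$fractions[["LL"]], 0)

  expect_error(induction_experiment(q, data.frame(Z = 1), "LL"),
               "self-activating genes")
  expect_error(induction_experiment(q, data.frame(A = 1, B = 1), "XX"))
})

test_that("sequential single-gene induction routes through the expected intermediate", {
  q <- get_quadrastable_fixture()
  # induce B only: low-low should move to low-high, not high-low
  yb <- induction_experiment(q, data.frame(A = 1, B = 15), "LL")
  f <- yb$stages[[1]]$fractions
  expect_gt(f[["LH"]], f[["HL"]])
  expect_gt(f[["LH"]] + f[["HH"]], 0.8)
})
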