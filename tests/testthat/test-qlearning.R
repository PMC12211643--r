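test_that("stage-2 OLS is exact on the saturated noiseless design", {
  p3 <- treatment_effect_preset(3)$params
  tab <- saturated_design_trial(p3)
  fit <- fit_stage2(tab)
  expect_equal(fit$beta2, c(0, 0, -0.5, 0), tolerance = 1e-12)
  expect_equal(fit$psi2, c(0.5, 0, 0.5), tolerance = 1e-12)
  # and agrees with the normal-equations oracle
  X <- with(tab, cbind(1, O1, A1, O1 * A1, A2, O2 * A2, A1 * A2))
  expect_equal(unname(c(fit$beta2, fit$psi2)), unname(ne_ols(X, tab$Y)),
               tolerance = 1e-12)
})

test_that("both stage fits match the normal-equations oracle on random tables", {
  for (s in 1:30) {
    tab <- random_small_trial(extra = 5 + s %% 17, seed = s)
    f2 <- fit_stage2(tab)
    X2 <- with(tab, cbind(1, O1, A1, O1 * A1, A2, O2 * A2, A1 * A2))
    expect_equal(unname(c(f2$beta2, f2$psi2)), unname(ne_ols(X2, tab$Y)),
                 tolerance = 1e-10)
    yhat1 <- pseudo_outcome(f2, tab)
    f1 <- fit_stage1(yhat1, tab)
    X1 <- with(tab, cbind(1, O1, A1, O1 * A1))
    expect_equal(unname(c(f1$beta1, f1$psi1)), unname(ne_ols(X1, yhat1)),
                 tolerance = 1e-10)
  }
})

test_that("degenerate outcomes give zero coefficients", {
  tab <- random_small_trial(seed = 2)
  tab$Y <- 0
  fit <- fit_stage2(tab)
  expect_equal(c(fit$beta2, fit$psi2), rep(0, 7))
  expect_equal(pseudo_outcome(fit, tab), rep(0, nrow(tab)))
  f1 <- fit_stage1(rep(3.25, nrow(tab)), tab)
  expect_equal(f1$beta1, c(3.25, 0))
  expect_equal(f1$psi1, c(0, 0))
})

test_that("rank deficiency is reported with the offending columns", {
  tab <- random_small_trial(seed = 3)
  tab$O2 <- tab$A1  # makes O2:A2 collinear with A1:A2
  expect_error(fit_stage2(tab), "collinear")
})

test_that("pseudo-outcome equals history effect plus |interaction effect|", {
  tab <- saturated_design_trial(treatment_effect_preset(1)$params)
  # true coefficients of the setting with stage-2 effect 1 +/- A1
  g5 <- treatment_effect_preset(5)$params$gamma
  fit5 <- structure(list(beta2 = g5[1:4], psi2 = g5[5:7]),
                    class = "stage2_fit")
  y5 <- pseudo_outcome(fit5, tab)
  # A1 = -1: |1 - 1| = 0, so pseudo-outcome is -gamma3*(-1)... = 0.5
  expect_equal(unique(y5[tab$A1 == -1]), 0.5)
  # A1 = +1: -0.5 + |1 + 1| = 1.5
  expect_equal(unique(y5[tab$A1 == 1]), 1.5)
  g4 <- treatment_effect_preset(4)$params$gamma
  fit4 <- structure(list(beta2 = g4[1:4], psi2 = g4[5:7]),
                    class = "stage2_fit")
  y4 <- pseudo_outcome(fit4, tab)
  expect_equal(unique(y4[tab$A1 == 1]), -0.5 + 0.99)
  expect_error(
    pseudo_outcome(fit4, transform(tab, O2 = NA)), "O2")
})

test_that("pseudo-outcome dominates the fitted Q2 at the realised action", {
  for (s in 1:10) {
    tab <- random_small_trial(extra = 20, seed = 100 + s)
    fit <- fit_stage2(tab)
    q2_obs <- with(tab, fit$beta2[1] + fit$beta2[2] * O1 + fit$beta2[3] * A1 +
                     fit$beta2[4] * O1 * A1 +
                     (fit$psi2[1] + fit$psi2[2] * O2 + fit$psi2[3] * A1) * A2)
    expect_true(all(pseudo_outcome(fit, tab) >= q2_obs - 1e-12))
  }
})

test_that("relabelling A2 flips stage-2 interaction signs but not stage 1", {
  tab <- random_small_trial(extra = 30, seed = 7)
  flipped <- transform(tab, A2 = -A2)
  f <- qlearn(tab)
  g <- qlearn(flipped)
  expect_equal(g$stage2$psi2, -f$stage2$psi2, tolerance = 1e-12)
  expect_equal(g$stage2$beta2, f$stage2$beta2, tolerance = 1e-12)
  expect_equal(g$pseudo_outcome, f$pseudo_outcome, tolerance = 1e-12)
  expect_equal(g$psi10, f$psi10, tolerance = 1e-12)
})

test_that("optimal rule is the sign of the decision score, ties to +1", {
  r <- optimal_rule(c(0.5, 0, 0.5), c(1, 1, 1))
  expect_equal(r$action, 1L)
  expect_false(r$tie)
  # the non-regular boundary: score exactly zero
  r0 <- optimal_rule(c(0.5, 0, 0.5), c(1, -1, -1))
  expect_equal(r0$action, 1L)
  expect_true(r0$tie)
  rz <- optimal_rule(c(0, 0), matrix(c(1, 1, 1, -1), 2, byrow = TRUE))
  expect_true(all(rz$tie))
  expect_error(optimal_rule(c(1, 2, 3), c(1, 1)), "per psi coefficient")
})

test_that("full-pipeline estimates are consistent for the presets", {
  # moderate n here; the large-n consistency check lives in the acceptance suite
  for (s in c(2, 5)) {
    preset <- treatment_effect_preset(s)
    tab <- simulate_trial(preset$params, 20000, seed = 50 + s)
    fit <- qlearn(tab)
    truth <- derive_truth(preset$params)
    expect_lt(abs(fit$psi10 - truth$psi10), 0.05)
    expect_lt(abs(fit$psi20 - truth$psi20), 0.05)
  }
})
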