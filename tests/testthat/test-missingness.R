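p1 <- treatment_effect_preset(1)$params

test_that("missingness_spec enforces the scenario/strength pairing", {
  expect_error(missingness_spec("S1", "weak", 0.2), "S1")
  expect_error(missingness_spec("S3a", "none", 0.2), "S1")
  sp <- missingness_spec("S3b", "weak", 0.4)
  expect_equal(sp$alpha, log(1.6))
  expect_equal(missingness_spec("S2a", "strong", 0.2)$alpha, log(3))
  expect_true(all(is.na(sp$alpha0)))
})

test_that("intercept-only models calibrate to the closed-form logit", {
  sp <- missingness_spec("S1", "none", 0.2)
  a0 <- calibrate_intercept(sp, p1, n_calib = 5000, seed = 1)
  expect_equal(a0, qlogis(0.2), tolerance = 1e-6)
  sp4 <- missingness_spec("S1", "none", 0.4)
  expect_equal(calibrate_intercept(sp4, p1, n_calib = 5000, seed = 1),
               qlogis(0.4), tolerance = 1e-6)
})

test_that("calibrated mechanisms hit their target on an independent draw", {
  cases <- list(list("S3a", "strong", 0.2), list("S4b", "weak", 0.4),
                list("S2b", "strong", 0.4))
  for (cs in cases) {
    sp <- calibrate_missingness(
      missingness_spec(cs[[1]], cs[[2]], cs[[3]]), p1,
      n_calib = 200000, seed = 21)
    fresh <- simulate_trial(p1, 200000, seed = 22)
    mask <- apply_missingness(fresh, sp, seed = 23)$mask
    primary <- if (cs[[1]] == "S4b") "M_A2" else "M_O2"
    expect_lt(abs(mean(mask[[primary]]) - cs[[3]]), 0.005)
  }
})

test_that("masking requires a complete trial and a calibrated spec", {
  tab <- simulate_trial(p1, 20, seed = 1)
  expect_error(apply_missingness(tab, missingness_spec("S3a", "weak", 0.2), 1),
               "uncalibrated")
  sp <- calibrate_missingness(missingness_spec("S1", "none", 0.2), p1,
                              n_calib = 5000, seed = 2)
  tab$Y[1] <- NA
  expect_error(apply_missingness(tab, sp, 1), "complete")
})

test_that("missingness indicators reproduce their odds ratios at large n", {
  sp <- calibrate_missingness(missingness_spec("S3a", "strong", 0.2), p1,
                              n_calib = 200000, seed = 31)
  tab <- simulate_trial(p1, 200000, seed = 32)
  mask <- apply_missingness(tab, sp, seed = 33)$mask
  # empirical OR of M_O2 across O1 strata at fixed A1 = -1
  sub <- tab$A1 == -1
  tb <- table(O1 = tab$O1[sub], M = mask$M_O2[sub])
  or_emp <- (tb["1", "1"] / tb["1", "0"]) / (tb["-1", "1"] / tb["-1", "0"])
  expect_lt(abs(or_emp - 3), 0.25)
  # logistic fit on the pre-deletion data recovers all the alphas
  fit <- glm(mask$M_O2 ~ I(tab$O1 == 1) + I(tab$A1 == 1), family = binomial)
  est <- coef(summary(fit))
  truth <- c(sp$alpha0[["O2"]], log(3), log(3))
  expect_true(all(abs(est[, "Estimate"] - truth) < 3 * est[, "Std. Error"]))
})

test_that("scenario m-DAGs constrain which variables can be missing", {
  tab <- simulate_trial(p1, 20000, seed = 41)
  # S1: independent mechanisms, A2 fully observed
  sp1 <- calibrate_missingness(missingness_spec("S1", "none", 0.4), p1,
                               n_calib = 5000, seed = 42)
  m1 <- apply_missingness(tab, sp1, seed = 43)
  expect_true(all(m1$mask$M_A2 == 0))
  expect_false(anyNA(m1$data$A2))
  # independence of the two S1 mechanisms (no propagation)
  expect_gt(sum(m1$mask$M_O2 == 1 & m1$mask$M_Y == 0), 0)
  # S2a/S3b: missing O2 forces A2 and Y missing
  for (scen in c("S2a", "S3b")) {
    sp <- calibrate_missingness(missingness_spec(scen, "strong", 0.2), p1,
                                n_calib = 20000, seed = 44)
    m <- apply_missingness(tab, sp, seed = 45)
    miss_o2 <- m$mask$M_O2 == 1
    expect_true(all(m$mask$M_A2[miss_o2] == 1))
    expect_true(all(m$mask$M_Y[miss_o2] == 1))
    expect_true(all(is.na(m$data$A2[miss_o2])))
    expect_true(all(is.na(m$data$Y[miss_o2])))
  }
  # S4a: O2 fully observed, missing A2 forces Y missing
  sp4 <- calibrate_missingness(missingness_spec("S4a", "weak", 0.2), p1,
                               n_calib = 20000, seed = 46)
  m4 <- apply_missingness(tab, sp4, seed = 47)
  expect_true(all(m4$mask$M_O2 == 0))
  expect_false(anyNA(m4$data$O2))
  expect_true(all(m4$mask$M_Y[m4$mask$M_A2 == 1] == 1))
  # O1 and A1 never missing under any scenario
  for (m in list(m1, m4)) {
    expect_false(anyNA(m$data$O1))
    expect_false(anyNA(m$data$A1))
  }
})

test_that("outcome-dependent mechanisms use pre-deletion Y values", {
  p2 <- treatment_effect_preset(2)$params
  sp <- calibrate_missingness(missingness_spec("S4b", "strong", 0.4), p2,
                              n_calib = 100000, seed = 51)
  tab <- simulate_trial(p2, 100000, seed = 52)
  m <- apply_missingness(tab, sp, seed = 53)
  # records with larger Y must be missing A2 more often (alpha2 > 0 on Y)
  hi <- tab$Y > median(tab$Y)
  expect_gt(mean(m$mask$M_A2[hi]), mean(m$mask$M_A2[!hi]) + 0.05)
})

test_that("achieved incomplete-case fraction is stable at study scale", {
  sp <- calibrate_missingness(missingness_spec("S3a", "weak", 0.2), p1,
                              n_calib = 100000, seed = 61)
  fracs <- vapply(1:40, function(r) {
    tab <- simulate_trial(p1, 500, seed = 100 + r)
    mean(apply_missingness(tab, sp, seed = 200 + r)$mask$M_O2)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.2), 0.01)
})
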