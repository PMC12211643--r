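p2 <- treatment_effect_preset(2)$params

masked_trial <- function(scenario = "S3a", strength = "weak", prop = 0.2,
                         n = 400, params = p2, seed = 1) {
  sp <- calibrate_missingness(missingness_spec(scenario, strength, prop),
                              params, n_calib = 20000,
                              seed = derive_seed(seed, "cal"))
  apply_missingness(simulate_trial(params, n, derive_seed(seed, "sim")),
                    sp, seed = derive_seed(seed, "mask"))$data
}

test_that("complete-case analysis subsets exactly the fully observed records", {
  full <- simulate_trial(p2, 30, seed = 1)
  expect_identical(complete_case(full), full)
  holey <- full
  holey$O2[c(2, 5)] <- NA
  holey$Y[c(5, 9, 12)] <- NA
  cc <- complete_case(holey)
  expect_equal(nrow(cc), 30 - 4)
  expect_false(anyNA(cc))
  expect_identical(rownames(cc), setdiff(rownames(holey),
                                         c("2", "5", "9", "12")))
  allgone <- full
  allgone$Y <- NA_real_
  expect_error(complete_case(allgone), "infeasible")
})

test_that("complete-case size tracks the calibrated missingness proportion", {
  sizes <- vapply(1:30, function(r) {
    nrow(complete_case(masked_trial(n = 500, seed = r,
                                    params = treatment_effect_preset(1)$params)))
  }, numeric(1))
  # S3a at 20%: incomplete cases are exactly the M_O2 = 1 records
  expect_lt(abs(mean(sizes) - 400), 3 * sd(sizes) / sqrt(30) + 1)
})

test_that("imputation returns m completed copies and never edits observed cells", {
  holey <- masked_trial(seed = 4)
  imps <- mice_impute(holey, m = 3, seed = 9)
  expect_length(imps, 3)
  obs <- !is.na(holey)
  for (imp in imps) {
    expect_false(anyNA(imp))
    expect_true(all(imp$O2 %in% c(-1, 1)))
    expect_true(all(imp$A2 %in% c(-1, 1)))
    expect_identical(as.matrix(imp)[obs], as.matrix(holey)[obs])
  }
  # imputations differ between copies and are seed-reproducible
  expect_false(identical(imps[[1]], imps[[2]]))
  expect_identical(mice_impute(holey, m = 3, seed = 9)[[2]], imps[[2]])
})

test_that("a complete table imputes to m identical copies", {
  full <- simulate_trial(p2, 50, seed = 2)
  imps <- mice_impute(full, m = 4, seed = 1)
  for (imp in imps) expect_identical(imp, full)
})

test_that("monotone blocks receive jointly consistent imputations", {
  holey <- masked_trial("S3b", "strong", 0.4, n = 500, seed = 6)
  block <- which(is.na(holey$O2))
  expect_true(all(is.na(holey$A2[block])))
  imps <- mice_impute(holey, m = 2, seed = 3)
  for (imp in imps) {
    expect_true(all(imp$O2[block] %in% c(-1, 1)))
    expect_true(all(imp$A2[block] %in% c(-1, 1)))
    expect_true(all(is.finite(imp$Y[block])))
  }
})

test_that("the imputation models use exactly the compatible predictor sets", {
  terms <- imputation_model_terms()
  expect_equal(terms$Y, c("O1", "A1", "O2", "A2", "O1:A1", "O2:A2", "A1:A2"))
  expect_equal(terms$O2, c("O1", "A1", "A2", "Y", "O1:A1", "A1:A2", "Y:A2"))
  expect_equal(terms$A2, c("O1", "A1", "O2", "Y", "O1:A1", "Y:O2", "Y:A1"))
})

test_that("default imputation count follows the missingness-proportion rule", {
  holey20 <- masked_trial(prop = 0.2, seed = 11,
                          params = treatment_effect_preset(1)$params)
  expect_length(mice_impute(holey20, n_cycles = 1, seed = 1), 20)
  holey40 <- masked_trial(prop = 0.4, seed = 12,
                          params = treatment_effect_preset(1)$params)
  expect_length(mice_impute(holey40, n_cycles = 1, seed = 1), 40)
  expect_error(mice_impute(holey20, m = 1, seed = 1), "at least 2")
  allmiss <- holey20
  allmiss$Y <- NA_real_
  expect_error(mice_impute(allmiss, m = 2, seed = 1), "no observed values")
})

test_that("Rubin pooling reproduces the combination formulas", {
  # hand arithmetic: points (0, 1), variances (1, 1)
  pe <- pool_rubin(c(0, 1), c(1, 1))
  expect_equal(pe$point, 0.5)
  expect_equal(pe$within_var, 1)
  expect_equal(pe$between_var, 0.5)
  expect_equal(pe$total_var, 1 + (1 + 1 / 2) * 0.5)  # 1.75
  expect_equal(pe$df, (2 - 1) * (1 + 1 / ((1 + 1 / 2) * 0.5))^2)
  expect_true(pe$ci_low <= pe$point && pe$point <= pe$ci_high)
  # identical points: no between-imputation variance, normal-limit interval
  pe0 <- pool_rubin(c(2, 2, 2), c(0.25, 0.25, 0.25))
  expect_equal(pe0$between_var, 0)
  expect_equal(pe0$total_var, 0.25)
  expect_equal(pe0$ci_high, 2 + qnorm(0.975) * 0.5)
  # the (1 + 1/m) inflation vanishes for large m
  set.seed(1)
  pts <- rnorm(5000)
  pe_big <- pool_rubin(pts, rep(1, 5000))
  expect_equal(pe_big$total_var, 1 + var(pts), tolerance = 0.001)
  expect_error(pool_rubin(1, 1), "at least 2")
  expect_error(pool_rubin(c(0, 1), c(1, -1)), "non-negative")
})

test_that("pooled Q-learning recovers a regular stage-1 effect", {
  holey <- masked_trial("S3a", "weak", 0.2, n = 2000, seed = 21)
  pooled <- mi_qlearn(holey, m = 5, seed = 22)
  expect_lt(abs(pooled$psi10$point - (-0.5)), 0.15)
  expect_equal(pooled$m, 5)
  expect_true(pooled$psi10$ci_low < pooled$psi10$point)
})
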