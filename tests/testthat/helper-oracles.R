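# Independent oracles and fixture builders used across the suite.

# Normal-equations least squares: the brute-force oracle the QR path is
# checked against.
ne_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# One record per cell of the full (O1, A1, O2, A2) factorial (16 records),
# with Y equal to the noiseless conditional outcome mean of `params`.
saturated_design_trial <- function(params) {
  cells <- expand.grid(O1 = c(-1, 1), A1 = c(-1, 1),
                       O2 = c(-1, 1), A2 = c(-1, 1))
  cells$Y <- mapply(function(o1, a1, o2, a2) {
    conditional_outcome_mean(params, o1, a1, o2, a2)
  }, cells$O1, cells$A1, cells$O2, cells$A2)
  cells
}

# Small random full-rank trial table (16 factorial cells guarantee rank,
# plus `extra` random records), with standard-normal noise on Y.
random_small_trial <- function(extra = 10, seed = 1) {
  base <- saturated_design_trial(treatment_effect_preset(1)$params)
  set.seed(seed)
  add <- data.frame(
    O1 = sample(c(-1, 1), extra, TRUE), A1 = sample(c(-1, 1), extra, TRUE),
    O2 = sample(c(-1, 1), extra, TRUE), A2 = sample(c(-1, 1), extra, TRUE),
    Y = 0)
  tab <- rbind(base, add)
  tab$Y <- rnorm(nrow(tab))
  tab
}

# Random generative parameterisation (for property-style checks that must
# hold beyond the five presets).
random_params <- function(seed) {
  set.seed(seed)
  generative_params(delta1 = rnorm(1, sd = 0.5), delta2 = rnorm(1, sd = 0.5),
                    gamma = rnorm(7, sd = 0.5))
}
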