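# True parameter values and Monte Carlo performance metrics.

#' Analytic true Q-learning parameters of a generative model
#'
#' Derives the population values of the stage-1 and stage-2 treatment
#' parameters implied by the generative model.  The stage-2 Q-function is
#' saturated in the terms the generative outcome model uses, so
#' `psi2 = (gamma5, gamma6, gamma7)` exactly.  The stage-1 values are the
#' projection of the expected pseudo-outcome onto the stage-1 design: with
#' \deqn{f(o_1, a_1) = \gamma_1 + \gamma_2 o_1 + \gamma_3 a_1 +
#'   \gamma_4 o_1 a_1 + p |\gamma_5 + \gamma_6 + \gamma_7 a_1| +
#'   (1 - p) |\gamma_5 - \gamma_6 + \gamma_7 a_1|,}
#' where \eqn{p = expit(\delta_1 o_1 + \delta_2 a_1)} is the responder
#' probability, the orthogonal -1/+1 design gives
#' \deqn{\psi_{10} = \tfrac14 \sum_{o_1, a_1} a_1 f(o_1, a_1), \qquad
#'       \psi_{11} = \tfrac14 \sum_{o_1, a_1} o_1 a_1 f(o_1, a_1).}
#'
#' @param params A [generative_params()] object.
#' @return A list `psi10`, `psi11`, `psi20`, `psi21`, `psi22`.
#' @export
#' @examples
#' derive_truth(treatment_effect_preset(4)$params)$psi10  # -0.01
derive_truth <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  g <- params$gamma
  f <- function(o1, a1) {
    p <- expit(params$delta1 * o1 + params$delta2 * a1)
    g[1] + g[2] * o1 + g[3] * a1 + g[4] * o1 * a1 +
      p * abs(g[5] + g[6] + g[7] * a1) +
      (1 - p) * abs(g[5] - g[6] + g[7] * a1)
  }
  cells <- expand.grid(o1 = c(-1, 1), a1 = c(-1, 1))
  fv <- mapply(f, cells$o1, cells$a1)
  list(
    psi10 = sum(cells$a1 * fv) / 4,
    psi11 = sum(cells$o1 * cells$a1 * fv) / 4,
    psi20 = g[5], psi21 = g[6], psi22 = g[7]
  )
}

#' Monte Carlo oracle for the true stage-1 parameter
#'
#' Brute-force check of [derive_truth()]: simulates a large complete trial,
#' forms the pseudo-outcome from the TRUE stage-2 coefficients (no
#' estimation), and projects it onto the stage-1 design by OLS.  Returns
#' the estimate and its Monte Carlo standard error.
#'
#' @param params A [generative_params()] object.
#' @param n Simulation size (default 1e6).
#' @param seed Integer seed.
#' @return A list `psi10`, `mc_se`.
#' @export
truth_mc_oracle <- function(params, n = 1e6, seed) {
  tab <- simulate_trial(params, n, seed)
  g <- params$gamma
  true_fit <- structure(
    list(beta2 = g[1:4], psi2 = g[5:7]), class = "stage2_fit")
  yhat1 <- pseudo_outcome(true_fit, tab)
  s1 <- fit_stage1(yhat1, tab)
  list(psi10 = s1$psi1[1], mc_se = sqrt(s1$vcov["A1", "A1"]))
}

#' Monte Carlo performance summary of an estimator
#'
#' Standard simulation-study metrics for a vector of replicate estimates:
#' bias (mean minus truth), empirical SE (sample SD across replicates),
#' MSE (empirical variance plus squared bias), Monte Carlo standard error
#' of the mean estimate (empirical SE / sqrt(n_reps)), and optionally the
#' mean bootstrap SE and the coverage of supplied confidence intervals.
#'
#' @param estimates Numeric vector of replicate estimates (>= 2).
#' @param true_value The true parameter value.
#' @param boot_ses Optional vector of per-replicate bootstrap (or other
#'   model-based) standard errors; summarised by their mean.
#' @param ci_low,ci_high Optional vectors of per-replicate confidence
#'   limits; summarised by coverage of `true_value`.
#' @return A one-row `data.frame`: `n_reps`, `bias`, `abs_bias`,
#'   `empirical_se`, `mse`, `mean_bootstrap_se`, `coverage`, `mc_error`.
#' @export
#' @examples
#' performance_summary(c(0, 1), true_value = 0)
performance_summary <- function(estimates, true_value, boot_ses = NULL,
                                ci_low = NULL, ci_high = NULL) {
  n_reps <- length(estimates)
  if (n_reps < 2) stop("need at least 2 replicate estimates")
  bias <- mean(estimates) - true_value
  emp_var <- stats::var(estimates)
  emp_se <- sqrt(emp_var)
  data.frame(
    n_reps = n_reps,
    bias = bias,
    abs_bias = abs(bias),
    empirical_se = emp_se,
    mse = emp_var + bias^2,
    mean_bootstrap_se = if (is.null(boot_ses)) NA_real_ else mean(boot_ses),
    coverage = if (is.null(ci_low)) {
      NA_real_
    } else {
      coverage_prop(ci_low, ci_high, true_value)
    },
    mc_error = emp_se / sqrt(n_reps)
  )
}

#' Coverage of confidence intervals
#'
#' Fraction of intervals containing the true value.
#'
#' @param ci_low,ci_high Numeric vectors of interval limits.
#' @param true_value The true parameter value.
#' @return A proportion in `[0, 1]`.
#' @export
coverage_prop <- function(ci_low, ci_high, true_value) {
  if (length(ci_low) != length(ci_high) || length(ci_low) < 1) {
    stop("ci_low and ci_high must be equal-length, non-empty vectors")
  }
  if (any(ci_low > ci_high)) stop("found an interval with low > high")
  mean(ci_low <= true_value & true_value <= ci_high)
}

#' Nonparametric bootstrap standard error of a pipeline estimate
#'
#' Resamples records with replacement (same size as the original trial),
#' re-runs the full estimation pipeline on each resample -- including any
#' missing-data handling the pipeline performs -- and returns the sample
#' SD of the bootstrap estimates.  A resample on which the pipeline fails
#' (e.g. no complete cases) is redrawn, with a capped number of retries.
#'
#' @param data A trial `data.frame` (may contain missing cells if the
#'   pipeline handles them).
#' @param pipeline A `function(trial) -> numeric(1)` estimator.
#' @param B Number of bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @param max_retries Redraw budget across all resamples (default `B`).
#' @return The bootstrap standard error (a single number).
#' @export
#' @examples
#' tab <- simulate_trial(treatment_effect_preset(2)$params, 200, seed = 3)
#' bootstrap_se(tab, function(d) qlearn(d)$psi10, B = 50, seed = 4)
bootstrap_se <- function(data, pipeline, B = 200L, seed, max_retries = B) {
  if (B < 2) stop("B must be at least 2")
  n <- nrow(data)
  with_seed(derive_seed(seed, "boot"), {
    est <- numeric(B)
    retries <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(pipeline(data[idx, , drop = FALSE]),
                        error = function(e) NULL)
        if (!is.null(val)) break
        retries <- retries + 1L
        if (retries > max_retries) {
          stop("bootstrap retry budget exhausted (pipeline kept failing)")
        }
      }
      est[b] <- val
    }
    if (retries > 0) {
      message(retries, " bootstrap resample(s) redrawn after pipeline failure")
    }
    stats::sd(est)
  })
}
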