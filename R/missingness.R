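# Missingness-DAG scenarios.
#
# Seven scenarios describe which variables drive missingness in the
# post-baseline variables O2, A2, Y (O1 and A1 are always complete):
#
#   S1  : M_O2 and M_Y each from intercept-only logistic models (MCAR).
#   S2a : M_O2 intercept-only; M_Y depends on A2.
#   S2b : M_O2 depends on Y;   M_Y depends on A2.
#   S3a : M_O2 depends on O1 and A1.
#   S3b : M_O2 depends on O1, A1 and Y.
#   S4a : M_A2 depends on O2.
#   S4b : M_A2 depends on O2 and Y.
#
# In S2*/S3* a missing O2 forces A2 and Y missing; in S4* a missing A2
# forces Y missing.  Binary predictors enter as 0/1 indicators [X = 1];
# Y enters on its raw continuous scale.  All non-intercept coefficients
# share one log odds ratio: log(1.6) for weak, log(3) for strong
# association.  Intercepts are calibrated so that each model's marginal
# missingness probability hits the target proportion.

.scenario_defs <- list(
  S1  = list(models = c("O2", "Y"),  propagate = "none"),
  S2a = list(models = c("O2", "Y"),  propagate = "O2"),
  S2b = list(models = c("O2", "Y"),  propagate = "O2"),
  S3a = list(models = "O2",          propagate = "O2"),
  S3b = list(models = "O2",          propagate = "O2"),
  S4a = list(models = "A2",          propagate = "A2"),
  S4b = list(models = "A2",          propagate = "A2")
)

#' Specify a missingness mechanism
#'
#' Builds the specification of one missingness scenario: which logistic
#' models generate the missingness indicators, the shared association
#' strength on the log-odds scale, and the marginal missingness proportion
#' each model's intercept is calibrated to.  See the package vignette for
#' the scenario taxonomy.
#'
#' @param scenario One of `"S1"`, `"S2a"`, `"S2b"`, `"S3a"`, `"S3b"`,
#'   `"S4a"`, `"S4b"`.
#' @param strength `"none"` (S1 only), `"weak"` (odds ratio 1.6) or
#'   `"strong"` (odds ratio 3) association between missingness indicators
#'   and their predictors.
#' @param target_prop Target marginal missingness proportion per model,
#'   in (0, 1); the study grid uses 0.2 and 0.4.
#' @return An object of class `missingness_spec` with uncalibrated
#'   intercepts (`alpha0` all `NA`); calibrate with
#'   [calibrate_missingness()] before applying.
#' @export
#' @examples
#' missingness_spec("S3a", "strong", 0.2)
missingness_spec <- function(scenario, strength, target_prop) {
  scenario <- match.arg(scenario, names(.scenario_defs))
  strength <- match.arg(strength, c("none", "weak", "strong"))
  if ((scenario == "S1") != (strength == "none")) {
    stop("strength must be \"none\" for scenario S1 and only for S1")
  }
  stopifnot(is.numeric(target_prop), length(target_prop) == 1,
            target_prop > 0, target_prop < 1)
  alpha <- switch(strength, none = 0, weak = log(1.6), strong = log(3))
  def <- .scenario_defs[[scenario]]
  alpha0 <- stats::setNames(rep(NA_real_, length(def$models)), def$models)
  structure(
    list(scenario = scenario, strength = strength, alpha = alpha,
         target_prop = target_prop, models = def$models,
         propagate = def$propagate, alpha0 = alpha0),
    class = "missingness_spec"
  )
}

#' @export
print.missingness_spec <- function(x, ...) {
  cat(sprintf("Missingness scenario %s (%s, target %g%%)\n",
              x$scenario, x$strength, 100 * x$target_prop))
  for (m in x$models) {
    a0 <- x$alpha0[[m]]
    cat(sprintf("  M_%s model: alpha0 = %s\n", m,
                if (is.na(a0)) "<uncalibrated>" else signif(a0, 5)))
  }
  invisible(x)
}

# Linear predictor (without intercept) of the missingness model for
# `target` ("O2", "A2" or "Y"), evaluated on COMPLETE pre-deletion data.
missingness_eta <- function(spec, target, data) {
  a <- spec$alpha
  key <- paste(spec$scenario, target, sep = ":")
  switch(
    key,
    "S1:O2"  = ,
    "S1:Y"   = ,
    "S2a:O2" = rep(0, nrow(data)),
    "S2a:Y"  = ,
    "S2b:Y"  = a * (data$A2 == 1),
    "S2b:O2" = a * data$Y,
    "S3a:O2" = a * (data$O1 == 1) + a * (data$A1 == 1),
    "S3b:O2" = a * (data$O1 == 1) + a * (data$A1 == 1) + a * data$Y,
    "S4a:A2" = a * (data$O2 == 1),
    "S4b:A2" = a * (data$O2 == 1) + a * data$Y,
    stop("scenario ", spec$scenario, " has no missingness model for ", target)
  )
}

# The model whose achieved proportion defines "20%/40% missingness":
# M_O2 for S1-S3, M_A2 for S4.
primary_model <- function(spec) {
  if (spec$scenario %in% c("S4a", "S4b")) "A2" else "O2"
}

# Monotone bisection for a0 such that mean(plogis(a0 + eta)) = target.
solve_intercept <- function(eta, target_prop, max_iter = 200L) {
  lo <- -30; hi <- 30
  f <- function(a0) mean(stats::plogis(a0 + eta)) - target_prop
  if (f(lo) > 0 || f(hi) < 0) stop("intercept bracket [-30, 30] failed")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) return((lo + hi) / 2)
  }
  stop(sprintf(
    "intercept bisection did not converge; last bracket [%g, %g]", lo, hi))
}

#' Calibrate missingness-model intercepts
#'
#' Chooses each missingness model's intercept so that the model's marginal
#' probability of missingness equals the target proportion, by monotone
#' bisection on a large freshly simulated complete trial under the given
#' generative parameters.  Intercepts are calibrated once per
#' (scenario, strength, target, treatment setting) and then frozen.
#'
#' `calibrate_missingness` calibrates every model of the spec and returns
#' the calibrated spec; `calibrate_intercept` returns just the intercept of
#' the scenario's primary model (M_O2 for S1-S3, M_A2 for S4).
#'
#' @param spec A [missingness_spec()].
#' @param params A [generative_params()] object (missingness models with a
#'   `Y` term depend on the outcome distribution, hence on the setting).
#' @param n_calib Size of the calibration sample (default 200000).
#' @param seed Integer seed for the calibration sample.
#' @param tol Tolerance on the achieved proportion in a self-check against
#'   an independent draw of the same size (default 0.005).
#' @return `calibrate_missingness`: the spec with all `alpha0` filled;
#'   `calibrate_intercept`: the primary model's intercept (a number).
#' @export
#' @examples
#' sp <- missingness_spec("S1", "none", 0.2)
#' p1 <- treatment_effect_preset(1)$params
#' calibrate_intercept(sp, p1, seed = 1)  # equals qlogis(0.2)
calibrate_missingness <- function(spec, params, n_calib = 200000L, seed,
                                  tol = 0.005) {
  stopifnot(inherits(spec, "missingness_spec"),
            inherits(params, "generative_params"))
  calib <- simulate_trial(params, n_calib, seed = derive_seed(seed, "calib"))
  check <- simulate_trial(params, n_calib, seed = derive_seed(seed, "check"))
  for (m in spec$models) {
    eta <- missingness_eta(spec, m, calib)
    a0 <- solve_intercept(eta, spec$target_prop)
    achieved <- mean(stats::plogis(a0 + missingness_eta(spec, m, check)))
    if (abs(achieved - spec$target_prop) > tol) {
      stop(sprintf(
        "calibrated M_%s intercept misses target on independent draw: %.4f vs %.4f",
        m, achieved, spec$target_prop))
    }
    spec$alpha0[[m]] <- a0
  }
  spec
}

#' @rdname calibrate_missingness
#' @export
calibrate_intercept <- function(spec, params, n_calib = 200000L, seed,
                                tol = 0.005) {
  calibrated <- calibrate_missingness(spec, params, n_calib, seed, tol)
  unname(calibrated$alpha0[[primary_model(calibrated)]])
}

#' Impose missingness on a complete trial
#'
#' Draws the missingness indicators from the spec's calibrated logistic
#' models, evaluated on the complete pre-deletion data (including `Y` where
#' the model involves `Y`), applies the scenario's deterministic
#' propagation (missing `O2` forces `A2` and `Y` missing in S2*/S3*;
#' missing `A2` forces `Y` missing in S4*), and blanks the masked cells.
#'
#' @param data A complete trial `data.frame`.
#' @param spec A calibrated [missingness_spec()].
#' @param seed Integer seed.
#' @return A list with `data` (the trial with `NA` in masked cells) and
#'   `mask` (a `data.frame` of 0/1 indicators `M_O2`, `M_A2`, `M_Y`).
#' @export
#' @examples
#' p1 <- treatment_effect_preset(1)$params
#' sp <- calibrate_missingness(missingness_spec("S1", "none", 0.2), p1,
#'                             n_calib = 10000, seed = 1)
#' masked <- apply_missingness(simulate_trial(p1, 100, 2), sp, seed = 3)
#' colMeans(masked$mask)
apply_missingness <- function(data, spec, seed) {
  stopifnot(inherits(spec, "missingness_spec"))
  validate_trial(data)
  if (anyNA(data)) stop("input trial must be complete (no missing cells)")
  if (anyNA(spec$alpha0)) {
    stop("spec has uncalibrated intercepts; run calibrate_missingness() first")
  }
  n <- nrow(data)
  mask <- data.frame(M_O2 = integer(n), M_A2 = integer(n), M_Y = integer(n))
  with_seed(seed, {
    for (m in spec$models) {
      p <- stats::plogis(spec$alpha0[[m]] + missingness_eta(spec, m, data))
      mask[[paste0("M_", m)]] <- as.integer(stats::runif(n) < p)
    }
  })
  if (spec$propagate == "O2") {
    mask$M_A2 <- pmax(mask$M_A2, mask$M_O2)
    mask$M_Y <- pmax(mask$M_Y, mask$M_O2)
  } else if (spec$propagate == "A2") {
    mask$M_Y <- pmax(mask$M_Y, mask$M_A2)
  }
  out <- data
  out$O2[mask$M_O2 == 1] <- NA_real_
  out$A2[mask$M_A2 == 1] <- NA_real_
  out$Y[mask$M_Y == 1] <- NA_real_
  list(data = out, mask = mask)
}
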