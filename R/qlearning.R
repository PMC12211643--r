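# Two-stage Q-learning by backward induction.
#
# Stage 2 regresses Y on (1, O1, A1, O1A1) + (1, O2, A1) * A2; the stage-1
# pseudo-outcome is the fitted stage-2 maximum over the stage-2 treatment,
# beta2' h2 + |psi2' h2|; stage 1 regresses the pseudo-outcome on
# (1, O1) + (1, O1) * A1.  The stage-k treatment main effect psi_k0 is the
# estimand of interest.

# QR-based OLS with rank check; returns coefficients, model-based
# covariance and residual sd.  Column names are used to report collinear
# columns on rank deficiency.
ols_fit <- function(X, y, tol = 1e-8) {
  qrx <- qr(X, tol = tol)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrx, y)
  res <- y - X %*% coefs
  df <- nrow(X) - ncol(X)
  s2 <- if (df > 0) sum(res^2) / df else NA_real_
  unpivot <- order(qrx$pivot)
  XtX_inv <- chol2inv(qr.R(qrx))[unpivot, unpivot, drop = FALSE]
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  list(coef = drop(coefs), vcov = s2 * XtX_inv,
       residual_sd = sqrt(s2), df = df)
}

stage2_design <- function(data) {
  with(data, cbind(
    "(Intercept)" = rep(1, nrow(data)), O1 = O1, A1 = A1, `O1:A1` = O1 * A1,
    A2 = A2, `O2:A2` = O2 * A2, `A1:A2` = A1 * A2))
}

stage1_design <- function(data) {
  with(data, cbind(
    "(Intercept)" = rep(1, nrow(data)), O1 = O1, A1 = A1, `O1:A1` = O1 * A1))
}

#' Fit the stage-2 Q-function
#'
#' Ordinary least squares of `Y` on the stage-2 design
#' `(1, O1, A1, O1*A1, A2, O2*A2, A1*A2)`.  The coefficients on the
#' `A2`-free columns are the history effects `beta2` (beta20..beta23); the
#' coefficients on the `A2` columns are the treatment-interaction effects
#' `psi2` (psi20, psi21, psi22), whose sign function is the estimated
#' optimal stage-2 rule.
#'
#' @param data A trial `data.frame` with `O2`, `A2`, `Y` observed for every
#'   supplied record (subset or impute upstream).
#' @return An object of class `stage2_fit`: `beta2` (length 4), `psi2`
#'   (length 3), `residual_sd`, `vcov` (7x7 model-based covariance).
#' @export
#' @examples
#' tab <- simulate_trial(treatment_effect_preset(2)$params, 2000, seed = 1)
#' fit_stage2(tab)$psi2
fit_stage2 <- function(data) {
  validate_trial(data)
  if (anyNA(data$O2) || anyNA(data$A2) || anyNA(data$Y)) {
    stop("fit_stage2 requires O2, A2 and Y observed for all records")
  }
  if (nrow(data) < 7) stop("need at least 7 records for the stage-2 design")
  X <- stage2_design(data)
  fit <- ols_fit(X, data$Y)
  structure(
    list(beta2 = unname(fit$coef[1:4]), psi2 = unname(fit$coef[5:7]),
         residual_sd = fit$residual_sd, vcov = fit$vcov, df = fit$df),
    class = "stage2_fit"
  )
}

#' Stage-1 pseudo-outcome
#'
#' For each record, the value of the fitted stage-2 Q-function maximised
#' over the stage-2 treatment:
#' \deqn{\hat Y_1 = \hat\beta_2' H_2 + |\hat\psi_2' H_2|,
#'   \quad H_2 = (1, O_1, A_1, O_1 A_1) / (1, O_2, A_1),}
#' with the stage-1 intermediate outcome fixed at zero (single terminal
#' outcome).  The absolute value is where non-regularity enters: when
#' `psi2' h2` is near zero, the maximum is a non-smooth functional.
#'
#' @param fit A [fit_stage2()] result.
#' @param data A trial `data.frame`; `O1`, `A1`, `O2` must be observed.
#' @return Numeric vector of pseudo-outcomes, one per record.
#' @export
pseudo_outcome <- function(fit, data) {
  stopifnot(inherits(fit, "stage2_fit"))
  validate_trial(data)
  if (anyNA(data$O2)) {
    stop("pseudo_outcome requires O2 observed; handle missingness upstream")
  }
  b <- fit$beta2; p <- fit$psi2
  hist_part <- b[1] + b[2] * data$O1 + b[3] * data$A1 + b[4] * data$O1 * data$A1
  trt_part <- p[1] + p[2] * data$O2 + p[3] * data$A1
  hist_part + abs(trt_part)
}

#' Fit the stage-1 Q-function
#'
#' Ordinary least squares of the stage-1 pseudo-outcome on
#' `(1, O1, A1, O1*A1)`, mapped to `beta1` = (beta10, beta11) and `psi1` =
#' (psi10, psi11).  `psi10`, the stage-1 treatment main effect, is the
#' primary estimand of the pipeline.
#'
#' @param pseudo Numeric vector of pseudo-outcomes (no `NA`).
#' @param data The trial `data.frame` the pseudo-outcomes belong to.
#' @return An object of class `stage1_fit`: `beta1`, `psi1`,
#'   `residual_sd`, `vcov`.
#' @export
fit_stage1 <- function(pseudo, data) {
  validate_trial(data)
  if (length(pseudo) != nrow(data) || anyNA(pseudo)) {
    stop("pseudo must be a complete vector with one value per record")
  }
  X <- stage1_design(data)
  fit <- ols_fit(X, pseudo)
  structure(
    list(beta1 = unname(fit$coef[1:2]), psi1 = unname(fit$coef[3:4]),
         residual_sd = fit$residual_sd, vcov = fit$vcov, df = fit$df),
    class = "stage1_fit"
  )
}

#' Optimal treatment decision from fitted interaction coefficients
#'
#' The estimated optimal action is `sign(psi' h)`.  An exact zero (the
#' non-regular boundary, where both actions are equally good under the
#' fitted model) is resolved to +1 and flagged.
#'
#' @param psi Numeric coefficient vector.
#' @param history Numeric history vector (or matrix with one row per
#'   record), conformable with `psi`.
#' @return A list with `action` (-1/+1, per record) and `tie` (logical,
#'   per record; `TRUE` where the inner product was exactly zero).
#' @export
#' @examples
#' optimal_rule(c(0.5, 0, 0.5), c(1, 1, -1))  # tie, resolved to +1
optimal_rule <- function(psi, history) {
  if (is.null(dim(history))) history <- matrix(history, nrow = 1)
  if (ncol(history) != length(psi)) {
    stop("history must have one column per psi coefficient")
  }
  score <- drop(history %*% psi)
  tie <- score == 0
  action <- ifelse(score >= 0, 1, -1)
  list(action = as.integer(action), tie = tie)
}

#' Two-stage Q-learning
#'
#' Runs the full backward induction on a complete (or completed) trial:
#' stage-2 fit, pseudo-outcome construction, stage-1 fit, and per-record
#' optimal rules at both stages.
#'
#' @param data A complete trial `data.frame` (use [complete_case()] or
#'   [mice_impute()] first if the trial has missing cells).
#' @return An object of class `qlearn_fit` with elements `stage2`,
#'   `pseudo_outcome`, `stage1`, scalar estimands `psi10` and `psi20` with
#'   model-based standard errors `se_psi10`, `se_psi20`, tie diagnostics
#'   and `n`.
#' @export
#' @examples
#' tab <- simulate_trial(treatment_effect_preset(5)$params, 5000, seed = 9)
#' fit <- qlearn(tab)
#' c(fit$psi10, fit$psi20)
qlearn <- function(data) {
  s2 <- fit_stage2(data)
  yhat1 <- pseudo_outcome(s2, data)
  s1 <- fit_stage1(yhat1, data)
  H2 <- cbind(1, data$O2, data$A1)
  H1 <- cbind(1, data$O1)
  rule2 <- optimal_rule(s2$psi2, H2)
  rule1 <- optimal_rule(s1$psi1, H1)
  structure(
    list(stage2 = s2, pseudo_outcome = yhat1, stage1 = s1,
         psi10 = s1$psi1[1], psi20 = s2$psi2[1],
         se_psi10 = sqrt(s1$vcov["A1", "A1"]),
         se_psi20 = sqrt(s2$vcov["A2", "A2"]),
         rule_stage2 = rule2, rule_stage1 = rule1,
         n_ties_stage2 = sum(rule2$tie), n = nrow(data)),
    class = "qlearn_fit"
  )
}

#' @export
print.qlearn_fit <- function(x, ...) {
  cat(sprintf("Two-stage Q-learning fit on n = %d records\n", x$n))
  cat(sprintf("  stage 1: psi10 = %8.4f (se %.4f), psi11 = %8.4f\n",
              x$psi10, x$se_psi10, x$stage1$psi1[2]))
  cat(sprintf("  stage 2: psi20 = %8.4f (se %.4f), psi21 = %8.4f, psi22 = %8.4f\n",
              x$psi20, x$se_psi20, x$stage2$psi2[2], x$stage2$psi2[3]))
  if (x$n_ties_stage2 > 0) {
    cat(sprintf("  note: %d record(s) on the stage-2 decision boundary\n",
                x$n_ties_stage2))
  }
  invisible(x)
}
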