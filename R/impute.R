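# Missing-data handling: complete-case analysis and multiple imputation by
# chained equations with proper (posterior-draw) univariate models.

#' Complete-case subset of a trial
#'
#' Drops every record with a missing value in any analysis variable,
#' preserving record order.
#'
#' @param data A trial `data.frame`.
#' @return The subset of fully observed records.
#' @export
complete_case <- function(data) {
  validate_trial(data)
  keep <- stats::complete.cases(data)
  if (!any(keep)) stop("no complete cases: complete-case analysis infeasible")
  data[keep, , drop = FALSE]
}

#' Imputation-model predictor sets
#'
#' The univariate conditional models used by the chained-equations engine.
#' Each incomplete variable is imputed from all other analysis variables
#' plus the interaction terms needed for compatibility with the two-stage
#' Q-learning analysis model: the outcome model carries the analysis-model
#' interactions `O1:A1`, `O2:A2`, `A1:A2`; the responder-status model
#' additionally carries `Y:A2`; the stage-2 treatment model carries `Y:O2`
#' and `Y:A1`.
#'
#' @return Named list of character vectors of predictor terms (intercept
#'   implicit), one per imputable variable.
#' @export
imputation_model_terms <- function() {
  list(
    Y  = c("O1", "A1", "O2", "A2", "O1:A1", "O2:A2", "A1:A2"),
    O2 = c("O1", "A1", "A2", "Y", "O1:A1", "A1:A2", "Y:A2"),
    A2 = c("O1", "A1", "O2", "Y", "O1:A1", "Y:O2", "Y:A1")
  )
}

# Design matrix (with intercept) from ":"-separated product terms.
term_matrix <- function(data, terms) {
  cols <- lapply(terms, function(tm) {
    Reduce(`*`, lapply(strsplit(tm, ":", fixed = TRUE)[[1]],
                       function(v) data[[v]]))
  })
  X <- do.call(cbind, c(list(rep(1, nrow(data))), cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}

# Logistic regression by iteratively reweighted least squares.
# Returns coefficient vector and unscaled inverse Fisher information.
# Falls back to a small ridge penalty on non-convergence or singularity
# (e.g. perfect separation), with a warning.
irls_logistic <- function(X, y01, ridge = 0, max_iter = 30L) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(ridge, p)
  for (i in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y01 - mu) / w
    XtW <- t(X * w)
    A <- XtW %*% X + pen
    new_beta <- tryCatch(solve(A, XtW %*% z), error = function(e) NULL)
    if (is.null(new_beta)) {
      if (ridge == 0) {
        warning("singular logistic imputation model; ridge-stabilised fit used")
        return(irls_logistic(X, y01, ridge = 1e-4 * mean(diag(crossprod(X)))))
      }
      stop("logistic imputation model unfittable even with ridge penalty")
    }
    delta <- max(abs(new_beta - beta))
    beta <- drop(new_beta)
    if (delta < 1e-8) {
      return(list(coef = beta, cov = solve(A)))
    }
  }
  if (ridge == 0) {
    warning("logistic imputation model did not converge; ridge-stabilised fit used")
    return(irls_logistic(X, y01, ridge = 1e-4 * mean(diag(crossprod(X)))))
  }
  list(coef = beta, cov = solve(A))
}

# One proper draw of a binary variable (-1/+1) for rows `draw_rows`,
# conditioning on current data via the given predictor terms.
draw_binary <- function(data, var, terms, obs_rows, draw_rows) {
  X <- term_matrix(data, terms)
  fit <- irls_logistic(X[obs_rows, , drop = FALSE],
                       as.numeric(data[[var]][obs_rows] == 1))
  L <- tryCatch(chol(fit$cov), error = function(e) {
    chol(fit$cov + diag(1e-10, ncol(fit$cov)))
  })
  beta_star <- fit$coef + drop(t(L) %*% stats::rnorm(length(fit$coef)))
  p_star <- stats::plogis(drop(X[draw_rows, , drop = FALSE] %*% beta_star))
  ifelse(stats::runif(length(p_star)) < p_star, 1, -1)
}

# One proper draw of the continuous outcome for rows `draw_rows`:
# scaled inverse-chi-square draw for the error variance, normal draw for
# the coefficients, then a predictive normal draw per record.
draw_gaussian <- function(data, var, terms, obs_rows, draw_rows) {
  X <- term_matrix(data, terms)
  Xo <- X[obs_rows, , drop = FALSE]
  y <- data[[var]][obs_rows]
  qrx <- qr(Xo)
  if (qrx$rank < ncol(Xo)) {
    warning("singular linear imputation model; ridge-stabilised fit used")
    A <- crossprod(Xo) + diag(1e-4 * mean(diag(crossprod(Xo))), ncol(Xo))
    beta_hat <- solve(A, crossprod(Xo, y))
    XtX_inv <- solve(A)
  } else {
    beta_hat <- qr.coef(qrx, y)
    unpivot <- order(qrx$pivot)
    XtX_inv <- chol2inv(qr.R(qrx))[unpivot, unpivot, drop = FALSE]
  }
  res <- y - drop(Xo %*% beta_hat)
  df <- max(length(y) - ncol(Xo), 1)
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  L <- chol(sigma2_star * XtX_inv)
  beta_star <- drop(beta_hat) + drop(t(L) %*% stats::rnorm(ncol(Xo)))
  mu <- drop(X[draw_rows, , drop = FALSE] %*% beta_star)
  mu + stats::rnorm(length(mu), sd = sqrt(sigma2_star))
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of an incomplete trial.  Each imputation
#' starts from a random fill (sampling observed values of each incomplete
#' variable) and then cycles through the incomplete variables in visit
#' order `O2`, `A2`, `Y`, refitting the univariate model of
#' [imputation_model_terms()] on records with the target observed
#' (predictors at their current values, interaction terms recomputed
#' passively) and drawing replacement values properly: model coefficients
#' (and, for `Y`, the error variance) are drawn from their approximate
#' posterior before each predictive draw.  Binary variables are imputed
#' from logistic draws mapped to -1/+1; `Y` from Bayesian linear
#' regression.  Observed cells are never altered.
#'
#' @param data A trial `data.frame`, possibly with missing `O2`, `A2`, `Y`
#'   (`O1`, `A1` must be complete).
#' @param m Number of imputations (>= 2).  Default follows the
#'   proportion rule of thumb: 20 when at most 30% of records are
#'   incomplete, 40 otherwise.
#' @param n_cycles Chained-equation sweeps per imputation (default 10).
#' @param seed Integer seed; imputation `k` uses a sub-seed derived from
#'   `(seed, k)` so single imputations are reproducible.
#' @return A list of `m` completed trial `data.frame`s (class `mi_set`),
#'   with the original missingness pattern attached as attribute `"miss"`.
#' @export
#' @examples
#' p2 <- treatment_effect_preset(2)$params
#' sp <- calibrate_missingness(missingness_spec("S3a", "weak", 0.2), p2,
#'                             n_calib = 20000, seed = 5)
#' masked <- apply_missingness(simulate_trial(p2, 300, 6), sp, seed = 7)
#' imps <- mice_impute(masked$data, m = 3, seed = 8)
#' length(imps)
mice_impute <- function(data, m = NULL, n_cycles = 10L, seed) {
  validate_trial(data)
  miss <- is.na(data[c("O2", "A2", "Y")])
  frac_incomplete <- mean(rowSums(miss) > 0)
  if (is.null(m)) m <- if (frac_incomplete <= 0.3) 20L else 40L
  if (m < 2) stop("m must be at least 2")
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  vars <- c("O2", "A2", "Y")[colSums(miss) > 0]
  for (v in vars) {
    if (all(is.na(data[[v]]))) {
      stop("variable ", v, " has no observed values; cannot impute")
    }
  }
  terms <- imputation_model_terms()
  out <- vector("list", m)
  for (k in seq_len(m)) {
    out[[k]] <- with_seed(derive_seed(seed, "imp", k), {
      if (length(vars) == 0) {
        data
      } else {
        cur <- data
        for (v in vars) {
          nas <- is.na(cur[[v]])
          obs <- cur[[v]][!nas]
          cur[[v]][nas] <- sample(obs, sum(nas), replace = TRUE)
        }
        for (cycle in seq_len(n_cycles)) {
          for (v in vars) {
            draw_rows <- which(miss[, v])
            obs_rows <- which(!miss[, v])
            cur[[v]][draw_rows] <- if (v == "Y") {
              draw_gaussian(cur, v, terms[[v]], obs_rows, draw_rows)
            } else {
              draw_binary(cur, v, terms[[v]], obs_rows, draw_rows)
            }
          }
        }
        cur
      }
    })
  }
  structure(out, class = "mi_set", miss = miss)
}
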