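#' Generative parameters for a two-stage SMART
#'
#' Bundles the coefficients of the generative models for a two-stage SMART
#' with binary baseline covariate `O1`, stage-1 treatment `A1`, binary
#' responder status `O2`, stage-2 treatment `A2` and continuous final
#' outcome `Y` (all binaries coded -1/+1):
#' \deqn{P(O2 = 1 | O1, A1) = expit(\delta_1 O1 + \delta_2 A1)}
#' \deqn{Y = \gamma_1 + \gamma_2 O1 + \gamma_3 A1 + \gamma_4 O1 A1 +
#'       \gamma_5 A2 + \gamma_6 O2 A2 + \gamma_7 A1 A2 + \epsilon,
#'       \quad \epsilon \sim N(0, \sigma^2).}
#'
#' @param delta1,delta2 Responder-model log-odds coefficients on `O1`, `A1`.
#' @param gamma Numeric vector of exactly 7 outcome-model coefficients.
#' @param noise_sd Standard deviation of the outcome noise (default 1).
#' @return An object of class `generative_params`.
#' @export
#' @examples
#' generative_params(0.5, 0.5, c(0, 0, -0.5, 0, 0, 0, 1))
generative_params <- function(delta1, delta2, gamma, noise_sd = 1) {
  stopifnot(is.numeric(delta1), length(delta1) == 1,
            is.numeric(delta2), length(delta2) == 1,
            is.numeric(noise_sd), length(noise_sd) == 1)
  if (length(gamma) != 7 || !is.numeric(gamma)) {
    stop("`gamma` must be a numeric vector of exactly 7 coefficients")
  }
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  structure(
    list(delta1 = as.numeric(delta1), delta2 = as.numeric(delta2),
         gamma = as.numeric(gamma), noise_sd = as.numeric(noise_sd)),
    class = "generative_params"
  )
}

#' @export
print.generative_params <- function(x, ...) {
  cat("Two-stage SMART generative parameters\n")
  cat(sprintf("  responder model: delta1 = %g, delta2 = %g\n",
              x$delta1, x$delta2))
  cat("  outcome model:  gamma =", paste(signif(x$gamma, 4), collapse = ", "),
      "\n")
  cat(sprintf("  noise sd: %g\n", x$noise_sd))
  invisible(x)
}

# Table of the five treatment-effect presets.  gamma columns are
# (g1, g2, g3, g4, g5, g6, g7); delta1 = delta2 = 0.5 throughout.
.preset_table <- list(
  `1` = list(gamma = c(0, 0,  0.0, 0, 0.0, 0, 0.00),
             label = "fully non-regular"),
  `2` = list(gamma = c(0, 0, -0.5, 0, 0.0, 0, 1.00),
             label = "fully regular"),
  `3` = list(gamma = c(0, 0, -0.5, 0, 0.5, 0, 0.50),
             label = "non-regular"),
  `4` = list(gamma = c(0, 0, -0.5, 0, 0.5, 0, 0.49),
             label = "regular-close-to-non-regular"),
  `5` = list(gamma = c(0, 0, -0.5, 0, 1.0, 0, 1.00),
             label = "non-regular")
)

#' Treatment-effect presets for the five regularity settings
#'
#' Returns the generative parameterisation of one of the five simulation
#' settings spanning the regularity spectrum: (1) no treatment effect at
#' either stage (fully non-regular); (2) a large stage-2 effect for everyone
#' and a stage-1 effect of -0.5 (fully regular); (3) a stage-2 effect for
#' half the participants only, no stage-1 effect (non-regular); (4) a very
#' weak stage-2 effect for half, a large one for the rest (regular but close
#' to non-regular, true stage-1 effect -0.01); (5) like (3) with a larger
#' stage-2 effect and a stage-1 effect of 0.5 (non-regular).
#'
#' @param setting_id Integer in 1..5.
#' @return A list with elements `setting_id`, `params`
#'   (a [generative_params()] object) and `regularity_label`.
#' @export
#' @examples
#' treatment_effect_preset(2)$params$gamma
treatment_effect_preset <- function(setting_id) {
  if (!(is.numeric(setting_id) && length(setting_id) == 1 &&
        !is.na(setting_id) && setting_id %in% 1:5)) {
    stop("`setting_id` must be a single integer in 1..5, got: ",
         deparse(substitute(setting_id)))
  }
  row <- .preset_table[[as.character(as.integer(setting_id))]]
  list(
    setting_id = as.integer(setting_id),
    params = generative_params(0.5, 0.5, row$gamma),
    regularity_label = row$label
  )
}

expit <- function(x) stats::plogis(x)

# Random -1/+1 with P(+1) = p (vectorised).
rsign <- function(n, p = 0.5) {
  ifelse(stats::runif(n) < p, 1, -1)
}

#' Simulate a complete two-stage SMART dataset
#'
#' Draws `O1`, `A1`, `A2` as independent -1/+1 with probability 0.5 each,
#' `O2` from the responder logistic model, and `Y` from the linear outcome
#' model with Gaussian noise (see [generative_params()]).  Stage-2
#' randomisation uses probability 0.5 in every `(A1, O2)` stratum, so a
#' simple per-record Bernoulli draw is distributionally identical.
#'
#' @param params A [generative_params()] object.
#' @param n Number of participants (>= 1).
#' @param seed Integer seed; the same seed always reproduces the same trial.
#' @return A `data.frame` with columns `O1`, `A1`, `O2`, `A2`, `Y`
#'   (a complete trial table, no missing cells).
#' @export
#' @examples
#' head(simulate_trial(treatment_effect_preset(1)$params, 10, seed = 1))
simulate_trial <- function(params, n, seed) {
  stopifnot(inherits(params, "generative_params"))
  if (!(is.numeric(n) && length(n) == 1 && n >= 1)) {
    stop("`n` must be a single integer >= 1")
  }
  n <- as.integer(n)
  with_seed(seed, {
    O1 <- rsign(n)
    A1 <- rsign(n)
    O2 <- rsign(n, p = expit(params$delta1 * O1 + params$delta2 * A1))
    A2 <- rsign(n)
    mu <- outcome_mean_vec(params, O1, A1, O2, A2)
    Y <- mu + stats::rnorm(n, sd = params$noise_sd)
    data.frame(O1 = O1, A1 = A1, O2 = O2, A2 = A2, Y = Y)
  })
}

# Vectorised noiseless outcome mean; no domain checks (internal).
outcome_mean_vec <- function(params, o1, a1, o2, a2) {
  g <- params$gamma
  g[1] + g[2] * o1 + g[3] * a1 + g[4] * o1 * a1 +
    g[5] * a2 + g[6] * o2 * a2 + g[7] * a1 * a2
}

#' Noiseless conditional mean of the outcome
#'
#' Evaluates the outcome-model mean
#' \eqn{\gamma_1 + \gamma_2 o_1 + \gamma_3 a_1 + \gamma_4 o_1 a_1 +
#' \gamma_5 a_2 + \gamma_6 o_2 a_2 + \gamma_7 a_1 a_2}
#' at one cell of the -1/+1 design.  Serves as the analytic oracle for the
#' simulator and for truth derivation.
#'
#' @param params A [generative_params()] object.
#' @param o1,a1,o2,a2 Scalars, each -1 or +1.
#' @return The conditional mean of `Y` in that cell (a single number).
#' @export
#' @examples
#' conditional_outcome_mean(treatment_effect_preset(3)$params, -1, -1, 1, 1)
conditional_outcome_mean <- function(params, o1, a1, o2, a2) {
  stopifnot(inherits(params, "generative_params"))
  args <- c(o1 = o1, a1 = a1, o2 = o2, a2 = a2)
  if (!all(args %in% c(-1, 1)) || length(args) != 4) {
    stop("all of o1, a1, o2, a2 must be scalars in {-1, 1}")
  }
  outcome_mean_vec(params, o1, a1, o2, a2)
}
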