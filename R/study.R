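# Factorial simulation study: enumeration, per-cell execution, aggregation.

.scenario_order <- c("S1", "S2a", "S2b", "S3a", "S3b", "S4a", "S4b")

#' Enumerate the simulation-study grid
#'
#' The method-free factorial design: 5 treatment-effect settings crossed
#' with 7 missingness scenarios, association strength (weak/strong, except
#' the MCAR scenario S1 which has none) and missingness proportion
#' (20%/40%) -- 5 x (2 + 6 x 2 x 2) = 130 cells in deterministic order.
#'
#' @return A `data.frame` with columns `cell_id`, `treatment_setting`,
#'   `missing_scenario`, `strength`, `target_prop`.
#' @export
#' @examples
#' nrow(enumerate_scenarios())  # 130
enumerate_scenarios <- function() {
  rows <- list()
  for (setting in 1:5) {
    for (scen in .scenario_order) {
      strengths <- if (scen == "S1") "none" else c("weak", "strong")
      for (strength in strengths) {
        for (prop in c(0.2, 0.4)) {
          rows[[length(rows) + 1]] <- data.frame(
            treatment_setting = setting, missing_scenario = scen,
            strength = strength, target_prop = prop)
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid$cell_id <- sprintf("T%d_%s_%s_p%02.0f", grid$treatment_setting,
                          grid$missing_scenario, grid$strength,
                          100 * grid$target_prop)
  grid[c("cell_id", "treatment_setting", "missing_scenario", "strength",
         "target_prop")]
}

# Default imputation count: 20 imputations for 20% missingness cells,
# 40 for 40% cells (rule of thumb m >= 100 * proportion missing).
default_m <- function(target_prop) if (target_prop <= 0.3) 20L else 40L

#' Run one (scenario x method) simulation cell
#'
#' For each replicate: simulate a complete trial, impose the calibrated
#' missingness mechanism, apply the missing-data method (complete-case
#' analysis, or chained-equations MI with Rubin pooling), run two-stage
#' Q-learning, and record the stage-1 and stage-2 treatment-effect
#' estimates.  Replicate estimates are then summarised against the
#' analytic truth of [derive_truth()].
#'
#' @param treatment_setting Integer 1..5, the treatment-effect preset.
#' @param missing_scenario,strength,target_prop Missingness cell factors
#'   (see [missingness_spec()]).
#' @param method `"CCA"` or `"MI"`.
#' @param n Participants per trial (default 500).
#' @param n_reps Number of replicate trials (default 1000).
#' @param root_seed Integer seed for the cell; replicate `r` derives its
#'   generation, masking and imputation streams from `(root_seed, r)`.
#' @param m Imputations per replicate (`NULL` = proportion rule).
#' @param n_cycles Chained-equation sweeps (default 10).
#' @param bootstrap If `TRUE`, compute per-replicate bootstrap standard
#'   errors and 95% confidence intervals for the stage-1 effect, enabling
#'   the `mean_bootstrap_se` and `coverage` columns.
#' @param B Bootstrap resamples per replicate (default 200).
#' @param max_fail_frac Cell fails if more than this fraction of
#'   replicates errors (default 0.01).
#' @return A `data.frame` with one row per estimand (`psi10`, `psi20`)
#'   carrying the cell identifiers and performance metrics.
#' @export
#' @examples
#' run_cell(1, "S1", "none", 0.2, "CCA", n = 200, n_reps = 5, root_seed = 1)
run_cell <- function(treatment_setting, missing_scenario, strength,
                     target_prop, method = c("CCA", "MI"), n = 500L,
                     n_reps = 1000L, root_seed, m = NULL, n_cycles = 10L,
                     bootstrap = FALSE, B = 200L, max_fail_frac = 0.01) {
  method <- match.arg(method)
  preset <- treatment_effect_preset(treatment_setting)
  spec <- calibrate_missingness(
    missingness_spec(missing_scenario, strength, target_prop),
    preset$params, seed = derive_seed(root_seed, "calibrate"))
  if (is.null(m)) m <- default_m(target_prop)
  truth <- derive_truth(preset$params)

  est10 <- est20 <- bse <- lo <- hi <- rep(NA_real_, n_reps)
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch(
      run_replicate(preset$params, spec, method, n, root_seed, r, m,
                    n_cycles, bootstrap, B),
      error = function(e) NULL)
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      next
    }
    est10[r] <- res$psi10
    est20[r] <- res$psi20
    bse[r] <- res$boot_se
    lo[r] <- res$ci_low
    hi[r] <- res$ci_high
  }
  if (n_fail > max_fail_frac * n_reps) {
    stop(sprintf("cell failed: %d of %d replicates errored", n_fail, n_reps))
  }
  ok <- !is.na(est10)
  have_ci <- bootstrap && !anyNA(lo[ok])
  sum10 <- performance_summary(
    est10[ok], truth$psi10,
    boot_ses = if (bootstrap) bse[ok],
    ci_low = if (have_ci) lo[ok], ci_high = if (have_ci) hi[ok])
  sum20 <- performance_summary(est20[ok], truth$psi20)
  ids <- data.frame(
    treatment_setting = treatment_setting,
    missing_scenario = missing_scenario, strength = strength,
    target_prop = target_prop, method = method, n = n,
    n_failed = n_fail)
  rbind(
    cbind(ids, estimand = "psi10", true_value = truth$psi10, sum10),
    cbind(ids, estimand = "psi20", true_value = truth$psi20, sum20))
}

# One replicate of a cell: simulate, mask, handle, estimate.
run_replicate <- function(params, spec, method, n, root_seed, r, m,
                          n_cycles, bootstrap, B) {
  trial <- simulate_trial(params, n, seed = derive_seed(root_seed, "trial", r))
  masked <- apply_missingness(trial, spec,
                              seed = derive_seed(root_seed, "mask", r))$data
  boot_se <- ci_low <- ci_high <- NA_real_
  if (method == "CCA") {
    fit <- qlearn(complete_case(masked))
    psi10 <- fit$psi10
    psi20 <- fit$psi20
    if (bootstrap) {
      boot_se <- bootstrap_se(masked, function(d) qlearn(complete_case(d))$psi10,
                              B = B, seed = derive_seed(root_seed, "boot", r))
      tq <- stats::qt(0.975, df = fit$n - 4)
      ci_low <- psi10 - tq * boot_se
      ci_high <- psi10 + tq * boot_se
    }
  } else {
    variance_fun <- if (bootstrap) {
      function(d, f) {
        v10 <- bootstrap_se(d, function(dd) qlearn(dd)$psi10, B = B,
                            seed = derive_seed(root_seed, "mi-boot", r))^2
        c(v10, f$se_psi20^2)
      }
    }
    pooled <- mi_qlearn(masked, m = m, n_cycles = n_cycles,
                        seed = derive_seed(root_seed, "mi", r),
                        variance_fun = variance_fun)
    psi10 <- pooled$psi10$point
    psi20 <- pooled$psi20$point
    boot_se <- pooled$psi10$se
    ci_low <- pooled$psi10$ci_low
    ci_high <- pooled$psi10$ci_high
  }
  list(psi10 = psi10, psi20 = psi20, boot_se = boot_se,
       ci_low = ci_low, ci_high = ci_high)
}

#' Run a (filtered) simulation study
#'
#' Executes every grid cell passing the config filters, for each requested
#' method, writing one long-format results row per (cell x method x
#' estimand).  Cells are independent work units with per-cell derived
#' seeds, so results are invariant to execution order and a rerun with the
#' same config is identical; with `out_dir` set, completed cells are
#' skipped on rerun (resumable).
#'
#' @param config A list: `settings`, `scenarios`, `strengths`,
#'   `target_props` (filters; `NULL` keeps all), `methods` (default
#'   `c("CCA", "MI")`), `n`, `n_reps`, `seed`, `m`, `n_cycles`,
#'   `bootstrap` (`"none"`, `"subset"`, `"all"`: `"subset"` restricts
#'   bootstrap SEs and coverage to treatment settings 1, 2, 4 under
#'   scenarios S1 and S2a), `B`.
#' @param out_dir Optional directory for per-cell CSVs and the combined
#'   `study_results.csv`.
#' @param verbose Print per-cell progress (default `TRUE`).
#' @return The combined long-format results `data.frame`.
#' @export
run_study <- function(config = list(), out_dir = NULL, verbose = TRUE) {
  cfg <- utils::modifyList(
    list(settings = NULL, scenarios = NULL, strengths = NULL,
         target_props = NULL, methods = c("CCA", "MI"), n = 500L,
         n_reps = 1000L, seed = 20260920L, m = NULL, n_cycles = 10L,
         bootstrap = "none", B = 200L),
    config)
  grid <- enumerate_scenarios()
  if (!is.null(cfg$settings)) {
    grid <- grid[grid$treatment_setting %in% cfg$settings, ]
  }
  if (!is.null(cfg$scenarios)) {
    grid <- grid[grid$missing_scenario %in% cfg$scenarios, ]
  }
  if (!is.null(cfg$strengths)) {
    grid <- grid[grid$strength %in% c(cfg$strengths, "none"), ]
  }
  if (!is.null(cfg$target_props)) {
    grid <- grid[grid$target_prop %in% cfg$target_props, ]
  }
  if (nrow(grid) == 0) stop("config filters select no grid cells")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  boot_subset <- function(row) {
    switch(cfg$bootstrap,
           none = FALSE,
           all = TRUE,
           subset = row$treatment_setting %in% c(1, 2, 4) &&
             row$missing_scenario %in% c("S1", "S2a"),
           stop("bootstrap must be one of none/subset/all"))
  }
  out <- list()
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    for (method in cfg$methods) {
      tag <- paste(row$cell_id, method, sep = "_")
      cell_file <- if (!is.null(out_dir)) {
        file.path(out_dir, paste0("cell_", tag, ".csv"))
      }
      if (!is.null(cell_file) && file.exists(cell_file)) {
        out[[tag]] <- utils::read.csv(cell_file)
        if (verbose) message("skipping completed cell ", tag)
        next
      }
      t0 <- Sys.time()
      res <- run_cell(
        row$treatment_setting, row$missing_scenario, row$strength,
        row$target_prop, method, n = cfg$n, n_reps = cfg$n_reps,
        root_seed = derive_seed(cfg$seed, "cell", tag), m = cfg$m,
        n_cycles = cfg$n_cycles, bootstrap = boot_subset(row), B = cfg$B)
      res$cell_id <- row$cell_id
      if (!is.null(cell_file)) {
        utils::write.csv(res, cell_file, row.names = FALSE)
      }
      if (verbose) {
        message(sprintf("cell %s done in %.1fs (bias_psi10 = %+.4f)", tag,
                        as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        res$bias[res$estimand == "psi10"]))
      }
      out[[tag]] <- res
    }
  }
  combined <- do.call(rbind, out)
  rownames(combined) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(combined, file.path(out_dir, "study_results.csv"),
                     row.names = FALSE)
  }
  combined
}

#' Bias plot for a study results table
#'
#' Absolute bias of the stage-1 effect by missingness scenario, method and
#' missingness proportion, faceted by association strength -- one panel
#' layout per treatment setting.  Requires ggplot2.
#'
#' @param results A results `data.frame` from [run_study()].
#' @param estimand Which estimand to plot (default `"psi10"`).
#' @return A ggplot object.
#' @export
plot_bias <- function(results, estimand = "psi10") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bias requires the ggplot2 package")
  }
  d <- results[results$estimand == estimand, ]
  d$pct <- factor(sprintf("%.0f%% missing", 100 * d$target_prop))
  ggplot2::ggplot(
    d, ggplot2::aes(x = missing_scenario, y = abs_bias, fill = method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(treatment_setting ~ pct + strength,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "missingness scenario",
                  y = sprintf("absolute bias of %s", estimand),
                  fill = NULL) +
    ggplot2::theme_bw()
}

utils::globalVariables(c("missing_scenario", "abs_bias", "method", "pct",
                         "treatment_setting", "strength"))
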