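#' Parameter-recovery study over replicate synthetic experiments
#'
#' Repeats simulate -> QC -> metrics -> fit for `n_reps` independent
#' replicates of the full design and summarises how well the pipeline
#' recovers the configured truths: the per-percent senescence-delay slope of
#' the endpoint model on the DOY of 50% senescence (with its model-implied
#' 75%-removal delay), and the percent difference in total leaf-level autumn
#' photosynthesis between the 75% leaf-removal group and the control.
#' Optionally checks empirical coverage of parametric bootstrap confidence
#' intervals for the model-implied 75%-removal delay.
#'
#' @param config A [sim_config()]; its `seed` is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param n_reps Number of replicate experiments.
#' @param seed Master seed for the replicate seed stream.
#' @param alpha Interaction-pruning threshold.
#' @param boot_nsim Bootstrap simulations per replicate for the coverage
#'   check; 0 (default) skips it.
#' @param cutoff_doy Modeling-window cutoff passed to [tree_metrics()].
#' @return An object of class `recovery_study`: per-replicate tibble
#'   `replicates` and a `summary` list (means, SDs, Monte-Carlo SEs, biases
#'   against the configured truths, bootstrap CI coverage when requested).
#' @export
recovery_study <- function(config, n_reps = 200, seed = 1L, alpha = 0.05,
                           boot_nsim = 0, cutoff_doy = 274L) {
  validate_sim_config(config)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_reps)
  spec <- model_spec("doy_50pct")

  reps <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    sim <- simulate_experiment(cfg)
    met <- tree_metrics(sim, cfg, cutoff_doy = cutoff_doy)

    auc75 <- mean(met$total_autumn_photo[met$treatment == "leaf_75"],
                  na.rm = TRUE)
    auc0 <- mean(met$total_autumn_photo[met$treatment == "control"],
                 na.rm = TRUE)
    photo_effect <- 100 * (auc75 / auc0 - 1)

    fit_row <- tryCatch({
      pr <- prune_interactions(spec, met, alpha = alpha)
      fit <- pr$fit
      sl <- fit$coefficients[fit$coefficients$term == "leaf_removal_pct", ]
      cover <- NA
      if (boot_nsim > 0 && fit$converged) {
        grid <- data.frame(leaf_removal_pct = c(0, 75),
                           bud_removal_pct = 0)
        ci <- tryCatch(
          bootstrap_ci(fit, grid, n_sim = boot_nsim, seed = rep_seeds[r]),
          error = function(e) NULL
        )
        if (!is.null(ci)) {
          # CI of the 75%-vs-control delay from the two prediction bootstraps
          diff_se <- sqrt(sum(ci$se_boot^2))
          delay_hat <- ci$fit[2] - ci$fit[1]
          truth <- 75 * config$true_senescence_delay_per_pct
          cover <- abs(delay_hat - truth) <= 1.96 * diff_se
        }
      }
      tibble::tibble(
        slope = sl$estimate, slope_se = sl$se, slope_p = sl$p,
        converged = fit$converged, singular = fit$singular,
        interaction_pruned = length(pr$fit$spec$interactions) == 0,
        ci_covered = cover
      )
    }, error = function(e) {
      tibble::tibble(slope = NA_real_, slope_se = NA_real_,
                     slope_p = NA_real_, converged = FALSE, singular = NA,
                     interaction_pruned = NA, ci_covered = NA)
    })
    dplyr::bind_cols(
      tibble::tibble(rep = r, rep_seed = rep_seeds[r],
                     photo_effect_pct = photo_effect,
                     n_doy50_defined = sum(met$doy_50pct_defined)),
      fit_row
    )
  })
  reps <- dplyr::bind_rows(reps)

  ok <- reps$converged & !is.na(reps$slope)
  slope <- reps$slope[ok]
  photo <- reps$photo_effect_pct
  summary <- list(
    n_reps = n_reps,
    n_fit_ok = sum(ok),
    truth_slope = config$true_senescence_delay_per_pct,
    mean_slope = mean(slope),
    sd_slope = sd(slope),
    mc_se_slope = sd(slope) / sqrt(length(slope)),
    bias_slope = mean(slope) - config$true_senescence_delay_per_pct,
    mean_delay_75 = 75 * mean(slope),
    mc_se_delay_75 = 75 * sd(slope) / sqrt(length(slope)),
    truth_photo_effect_pct = config$true_photo_effect_pct,
    mean_photo_effect_pct = mean(photo),
    sd_photo_effect_pct = sd(photo),
    mc_se_photo_effect_pct = sd(photo) / sqrt(length(photo)),
    bias_photo_effect_pct = mean(photo) - config$true_photo_effect_pct,
    ci_coverage = if (boot_nsim > 0) mean(reps$ci_covered, na.rm = TRUE)
                  else NA_real_
  )
  structure(list(replicates = reps, summary = summary),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  s <- x$summary
  cat("<recovery_study> ", s$n_reps, " replicates (", s$n_fit_ok,
      " converged fits)\n", sep = "")
  cat(sprintf("  senescence delay slope: truth %.4f, recovered %.4f +/- %.4f (MC SE)\n",
              s$truth_slope, s$mean_slope, s$mc_se_slope))
  cat(sprintf("  implied 75%% delay: %.2f days +/- %.2f\n",
              s$mean_delay_75, s$mc_se_delay_75))
  cat(sprintf("  photosynthesis effect: truth %.1f%%, recovered %.2f%% +/- %.2f\n",
              s$truth_photo_effect_pct, s$mean_photo_effect_pct,
              s$mc_se_photo_effect_pct))
  if (!is.na(s$ci_coverage))
    cat(sprintf("  bootstrap 95%% CI coverage: %.1f%%\n", 100 * s$ci_coverage))
  invisible(x)
}
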