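#' Simulation configuration for a synthetic defoliation experiment
#'
#' Bundles the event calendar, measurement schedules, true treatment effects
#' and noise levels that drive the synthetic-experiment generator. Defaults
#' reproduce the study conditions: two leaf-removal events (DOY 163 and 225)
#' and one bud-removal event (DOY 216) in a 2020 calendar, six photosynthesis
#' campaigns and thirteen count/SPAD campaigns from mid-August to late
#' November, and true effects of a 0.0575-day senescence delay per percent of
#' leaves removed (4.31 days at 75% removal) and a 14% increase in total
#' leaf-level autumn photosynthesis at 75% removal. The bud arm is a true
#' null by default but settable for power studies.
#'
#' @param seed Integer seed for the generator.
#' @param event_doys Named list with integer days of year `leaf_removal_1`,
#'   `bud_removal`, `leaf_removal_2`.
#' @param photosynthesis_doys Six strictly increasing integer DOYs, the first
#'   day of each gas-exchange measurement interval.
#' @param counts_spad_doys Thirteen strictly increasing integer DOYs for the
#'   leaf/bud count and SPAD campaigns.
#' @param true_senescence_delay_per_pct Days of delay of the senescence
#'   midpoint per percent of leaves removed (simulation truth).
#' @param true_senescence_delay_per_pct_bud Same, per percent of buds removed;
#'   0 by default (the bud-arm null).
#' @param true_photo_effect_pct Percent increase in the noise-free
#'   photosynthesis AUC at 75% leaf removal relative to control.
#' @param regrowth_gain Expected fraction of a removal deficit regrown per
#'   regrowth step (dimensionless, >= 0).
#' @param leaf_count_mean,leaf_count_sd Initial leaf count distribution.
#' @param bud_count_mean,bud_count_sd Initial bud count distribution.
#' @param spad_plateau Pre-senescence SPAD plateau (dimensionless).
#' @param senescence_midpoint_doy Baseline DOY at which the senescence
#'   logistic reaches half of the plateau for an untreated tree.
#' @param senescence_steepness Logistic time scale of chlorophyll decline, days.
#' @param leaf_fall_lag Days by which leaf abscission lags the chlorophyll
#'   midpoint.
#' @param leaf_fall_steepness Logistic time scale of leaf fall, days
#'   (abscission is steeper than chlorophyll loss).
#' @param a_max Early-autumn net photosynthesis amplitude, umol m-2 s-1.
#' @param photo_midpoint_doy,photo_steepness Logistic parameters of the
#'   seasonal photosynthesis decline.
#' @param count_sd,spad_sd,photo_sd Measurement noise SDs for counts, SPAD
#'   and net photosynthesis.
#' @param tree_sd,block_sd SDs (days) of tree- and block-level random shifts
#'   of the senescence midpoint. Tree shifts are truncated at +/- 2 SD: the
#'   campaign calendar brackets the cohort's senescence, so trees still
#'   green after the final campaign are out of scope by design.
#' @param photo_tree_cv Relative SD of the tree-level multiplicative
#'   photosynthesis amplitude effect.
#' @param qc_artifact_rate Fraction of photosynthesis records given an
#'   implausible covariate (negative stomatal conductance) to exercise QC.
#' @param small_leaf_rate Fraction of photosynthesis records measured on a
#'   leaf too small to fill the chamber (covered fraction < 1).
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$event_doys$leaf_removal_1
sim_config <- function(seed = 1L,
                       event_doys = list(leaf_removal_1 = 163L,
                                         bud_removal = 216L,
                                         leaf_removal_2 = 225L),
                       photosynthesis_doys = c(240L, 258L, 276L, 294L,
                                               312L, 330L),
                       counts_spad_doys = c(228L, 240L, 254L, 266L, 274L,
                                            281L, 288L, 295L, 302L, 309L,
                                            316L, 323L, 330L),
                       true_senescence_delay_per_pct = 4.31 / 75,
                       true_senescence_delay_per_pct_bud = 0,
                       true_photo_effect_pct = 14,
                       regrowth_gain = 0.5,
                       leaf_count_mean = 600, leaf_count_sd = 100,
                       bud_count_mean = 40, bud_count_sd = 8,
                       spad_plateau = 40,
                       senescence_midpoint_doy = 300,
                       senescence_steepness = 8,
                       leaf_fall_lag = 15,
                       leaf_fall_steepness = 5,
                       a_max = 8,
                       photo_midpoint_doy = 280, photo_steepness = 9,
                       count_sd = 0, spad_sd = 2, photo_sd = 0.5,
                       tree_sd = 12, block_sd = 2,
                       photo_tree_cv = 0.15,
                       qc_artifact_rate = 0.05,
                       small_leaf_rate = 0.15) {
  cfg <- structure(
    list(
      seed = as.integer(seed),
      event_doys = lapply(event_doys, as.integer),
      photosynthesis_doys = as.integer(photosynthesis_doys),
      counts_spad_doys = as.integer(counts_spad_doys),
      true_senescence_delay_per_pct = true_senescence_delay_per_pct,
      true_senescence_delay_per_pct_bud = true_senescence_delay_per_pct_bud,
      true_photo_effect_pct = true_photo_effect_pct,
      regrowth_gain = regrowth_gain,
      leaf_count_mean = leaf_count_mean, leaf_count_sd = leaf_count_sd,
      bud_count_mean = bud_count_mean, bud_count_sd = bud_count_sd,
      spad_plateau = spad_plateau,
      senescence_midpoint_doy = senescence_midpoint_doy,
      senescence_steepness = senescence_steepness,
      leaf_fall_lag = leaf_fall_lag,
      leaf_fall_steepness = leaf_fall_steepness,
      a_max = a_max,
      photo_midpoint_doy = photo_midpoint_doy,
      photo_steepness = photo_steepness,
      count_sd = count_sd, spad_sd = spad_sd, photo_sd = photo_sd,
      tree_sd = tree_sd, block_sd = block_sd,
      photo_tree_cv = photo_tree_cv,
      qc_artifact_rate = qc_artifact_rate,
      small_leaf_rate = small_leaf_rate
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ev <- cfg$event_doys
  if (!setequal(names(ev), c("leaf_removal_1", "bud_removal", "leaf_removal_2")))
    stop("event_doys must name leaf_removal_1, bud_removal, leaf_removal_2")
  if (!(ev$leaf_removal_1 < ev$bud_removal &&
        ev$bud_removal < ev$leaf_removal_2))
    stop("events must be ordered: leaf removal 1 < bud removal < leaf removal 2")
  if (length(cfg$photosynthesis_doys) != 6 ||
      any(diff(cfg$photosynthesis_doys) <= 0))
    stop("photosynthesis_doys must be 6 strictly increasing DOYs")
  if (length(cfg$counts_spad_doys) != 13 ||
      any(diff(cfg$counts_spad_doys) <= 0))
    stop("counts_spad_doys must be 13 strictly increasing DOYs")
  if (ev$leaf_removal_2 > min(cfg$counts_spad_doys))
    stop("removal events must precede the count/SPAD campaigns")
  sds <- c(cfg$leaf_count_sd, cfg$bud_count_sd, cfg$count_sd, cfg$spad_sd,
           cfg$photo_sd, cfg$tree_sd, cfg$block_sd, cfg$photo_tree_cv)
  if (any(sds < 0)) stop("all noise SDs must be >= 0")
  if (cfg$regrowth_gain < 0) stop("regrowth_gain must be >= 0")
  if (cfg$qc_artifact_rate < 0 || cfg$qc_artifact_rate > 1)
    stop("qc_artifact_rate must be in [0, 1]")
  if (cfg$small_leaf_rate < 0 || cfg$small_leaf_rate > 1)
    stop("small_leaf_rate must be in [0, 1]")
  if (cfg$spad_plateau <= 0 || cfg$a_max <= 0 ||
      cfg$senescence_steepness <= 0 || cfg$photo_steepness <= 0 ||
      cfg$leaf_fall_steepness <= 0)
    stop("plateau, amplitude and steepness parameters must be positive")
  if (cfg$leaf_fall_lag < 0) stop("leaf_fall_lag must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  events (DOY): leaf", x$event_doys$leaf_removal_1,
      "| bud", x$event_doys$bud_removal,
      "| leaf", x$event_doys$leaf_removal_2, "\n")
  cat("  schedules:", length(x$photosynthesis_doys), "photosynthesis +",
      length(x$counts_spad_doys), "count/SPAD campaigns\n")
  cat("  truths: delay", signif(x$true_senescence_delay_per_pct, 4),
      "d/% leaf; photo effect", x$true_photo_effect_pct, "% at 75%\n")
  invisible(x)
}

#' Strip all noise from a simulation configuration
#'
#' Sets every noise SD, random-effect SD and QC artifact rate to zero, so the
#' generator returns its deterministic expectation and downstream metrics
#' recover the configured truths exactly (the noiseless-limit checks).
#'
#' @param cfg A [sim_config()].
#' @return The modified `sim_config`.
#' @export
noise_free <- function(cfg) {
  cfg$leaf_count_sd <- 0; cfg$bud_count_sd <- 0
  cfg$count_sd <- 0; cfg$spad_sd <- 0; cfg$photo_sd <- 0
  cfg$tree_sd <- 0; cfg$block_sd <- 0; cfg$photo_tree_cv <- 0
  cfg$qc_artifact_rate <- 0; cfg$small_leaf_rate <- 0
  cfg
}
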