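# Synthetic-experiment generator.
#
# Latent per-tree state (initial organ counts, senescence midpoint shift,
# photosynthesis amplitude factor) and all noise streams are derived from
# (config$seed, tree_id, purpose) hashes, so the counts, SPAD and
# photosynthesis tables of the same tree are mutually consistent no matter
# which generator function is called first or on which subset of trees.

# deterministic 31-bit stream seed from the master seed and string labels
hash_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (s in as.character(c(...))) {
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# declining logistic in [0, 1]: 1 well before `midpoint`, 1/2 at it, 0 after
senescence_survival <- function(doy, midpoint, steepness) {
  1 / (1 + exp((doy - midpoint) / steepness))
}

block_effects <- function(config) {
  vapply(1:10, function(b) {
    set.seed(hash_seed(config$seed, "block", b))
    rnorm(1, 0, config$block_sd)
  }, numeric(1))
}

tree_latents <- function(design, config) {
  stopifnot(is.data.frame(design), nrow(design) >= 1)
  blk <- block_effects(config)
  n <- nrow(design)
  leaf0 <- bud0 <- midpoint <- photo_factor <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(hash_seed(config$seed, "latent", design$tree_id[i]))
    mu_leaf <- config$leaf_count_mean *
      (1 + 0.05 * (design$leaf_out_group[i] - 3))
    leaf0[i] <- max(1, round(rnorm(1, mu_leaf, config$leaf_count_sd)))
    bud0[i] <- max(1, round(rnorm(1, config$bud_count_mean,
                                  config$bud_count_sd)))
    # truncated at +/- 2 SD: the campaign calendar brackets the cohort's
    # senescence, so unbounded Gaussian tails (trees still green after the
    # last campaign) are out of scope by design
    tree_shift <- qnorm(runif(1, pnorm(-2), pnorm(2))) * config$tree_sd
    photo_factor[i] <- max(0.1, 1 + rnorm(1, 0, config$photo_tree_cv))
    midpoint[i] <- config$senescence_midpoint_doy +
      config$true_senescence_delay_per_pct * design$leaf_removal_pct[i] +
      config$true_senescence_delay_per_pct_bud * design$bud_removal_pct[i] +
      blk[design$block_id[i]] + tree_shift
  }
  tibble::tibble(tree_id = design$tree_id, leaf0 = leaf0, bud0 = bud0,
                 midpoint = midpoint, photo_factor = photo_factor)
}

removal_remainder <- function(count, pct) {
  # round() uses round-half-to-even, the documented tie rule
  round((1 - pct / 100) * count)
}

regrowth_draw <- function(expected, deterministic) {
  if (deterministic) round(expected) else rpois(1, expected)
}

#' Simulate dated leaf and bud counts for trees
#'
#' Produces one leaf and one bud count per count/SPAD campaign day, plus
#' paired pre/post observations of the affected organ on each removal day.
#' Leaf removals apply the tree's percentage twice (the second removal also
#' takes back the compensatory regrowth accumulated since the first); the
#' single bud removal applies the bud percentage. Between events, removed
#' organs regrow with an expected gain of `regrowth_gain` times the current
#' deficit (Poisson noise; deterministic expectation when `count_sd = 0`).
#' Late-season leaf counts decline to zero along the tree's senescence
#' logistic; bud counts persist.
#'
#' @param design One or more rows of [generate_design()] output.
#' @param config A [sim_config()].
#' @return A tibble with columns `tree_id`, `doy`, `organ` (`"leaf"` or
#'   `"bud"`), `count`, `event_phase` (`"pre"`, `"post"`, `"none"`).
#' @export
simulate_counts <- function(design, config) {
  validate_sim_config(config)
  lat <- tree_latents(design, config)
  ev <- config$event_doys
  doys <- config$counts_spad_doys
  det <- config$count_sd == 0

  nd <- length(doys)
  leaf_doys <- c(ev$leaf_removal_1, ev$leaf_removal_1,
                 ev$leaf_removal_2, ev$leaf_removal_2, doys)
  bud_doys <- c(ev$bud_removal, ev$bud_removal, doys)
  leaf_phase <- c("pre", "post", "pre", "post", rep("none", nd))
  bud_phase <- c("pre", "post", rep("none", nd))
  rows_per_tree <- length(leaf_doys) + length(bud_doys)

  counts <- lapply(seq_len(nrow(design)), function(i) {
    lt <- lat[i, ]
    set.seed(hash_seed(config$seed, "counts", design$tree_id[i]))

    # leaves: two removal events, regrowth between them, senescent decline
    pre1 <- lt$leaf0
    post1 <- removal_remainder(pre1, design$leaf_removal_pct[i])
    gain <- regrowth_draw(config$regrowth_gain * (pre1 - post1), det)
    pre2 <- post1 + gain
    post2 <- removal_remainder(pre2, design$leaf_removal_pct[i])
    # abscission lags chlorophyll loss and proceeds on its own steeper scale
    surv <- senescence_survival(doys, lt$midpoint + config$leaf_fall_lag,
                                config$leaf_fall_steepness)
    leaf_sched <- pmax(0L, as.integer(round(
      post2 * surv + rnorm(nd, 0, config$count_sd * surv))))

    # buds: one removal event, stepwise regrowth toward the deficit
    bpre <- lt$bud0
    bpost <- removal_remainder(bpre, design$bud_removal_pct[i])
    current <- bpost
    bud_sched <- integer(nd)
    for (k in seq_len(nd)) {
      deficit <- max(0, bpre - current)
      current <- current +
        regrowth_draw(config$regrowth_gain / 4 * deficit, det)
      bud_sched[k] <- current
    }
    as.integer(c(pre1, post1, pre2, post2, leaf_sched,
                 bpre, bpost, bud_sched))
  })

  tibble::tibble(
    tree_id = rep(design$tree_id, each = rows_per_tree),
    doy = rep(as.integer(c(leaf_doys, bud_doys)), nrow(design)),
    organ = rep(rep(c("leaf", "bud"), c(length(leaf_doys), length(bud_doys))),
                nrow(design)),
    count = unlist(counts),
    event_phase = rep(c(leaf_phase, bud_phase), nrow(design))
  )
}

#' Simulate per-tree average SPAD chlorophyll series
#'
#' Average SPAD per campaign day follows a decreasing logistic from the
#' plateau toward zero. The tree's midpoint day is the baseline midpoint
#' shifted by the configured per-percent senescence delay times the leaf
#' (and, if configured, bud) removal percentage, plus block- and tree-level
#' random shifts; Gaussian measurement noise is added on top and values are
#' clamped at zero.
#'
#' @inheritParams simulate_counts
#' @return A tibble with columns `tree_id`, `doy`, `avg_spad`.
#' @export
simulate_chlorophyll <- function(design, config) {
  validate_sim_config(config)
  lat <- tree_latents(design, config)
  doys <- config$counts_spad_doys
  spad <- lapply(seq_len(nrow(design)), function(i) {
    set.seed(hash_seed(config$seed, "spad", design$tree_id[i]))
    mu <- config$spad_plateau *
      senescence_survival(doys, lat$midpoint[i], config$senescence_steepness)
    pmax(0, mu + rnorm(length(doys), 0, config$spad_sd))
  })
  tibble::tibble(
    tree_id = rep(design$tree_id, each = length(doys)),
    doy = rep(doys, nrow(design)),
    avg_spad = unlist(spad)
  )
}

#' Simulate leaf-level net photosynthesis records
#'
#' One record per tree and gas-exchange campaign. The noise-free rate is a
#' seasonal declining logistic scaled by a treatment amplitude chosen so that
#' the time-integral for a 75% leaf-removal tree exceeds the control's by
#' exactly `true_photo_effect_pct` percent (linear in the removal
#' percentage). A `small_leaf_rate` fraction of records is measured on a leaf
#' that does not fill the chamber: their recorded rate is the chamber-average
#' value (true rate times the covered fraction), which the QC area correction
#' restores. A `qc_artifact_rate` fraction carries an implausible negative
#' stomatal conductance. Trees whose simulated leaf count has reached zero by
#' a campaign are flagged leafless and record a zero rate.
#'
#' @inheritParams simulate_counts
#' @return A tibble with columns `tree_id`, `doy`, `a_net`,
#'   `covered_fraction`, `gsw`, `leafless_flag`.
#' @export
simulate_photosynthesis <- function(design, config) {
  validate_sim_config(config)
  lat <- tree_latents(design, config)
  doys <- config$photosynthesis_doys
  counts <- simulate_counts(design, config)
  leaf_counts <- counts[counts$organ == "leaf" & counts$event_phase == "none", ]
  lc_split <- split(leaf_counts[, c("doy", "count")], leaf_counts$tree_id)
  nd <- length(doys)
  shape <- senescence_survival(doys, config$photo_midpoint_doy,
                               config$photo_steepness)

  out <- lapply(seq_len(nrow(design)), function(i) {
    id <- design$tree_id[i]
    lc <- lc_split[[id]]
    set.seed(hash_seed(config$seed, "photo", id))

    amp <- config$a_max * lat$photo_factor[i] *
      (1 + config$true_photo_effect_pct / 100 *
         design$leaf_removal_pct[i] / 75)
    a_true <- amp * shape
    a_obs <- a_true + rnorm(nd, 0, config$photo_sd)

    # leafless when the latest count campaign at or before the photosynthesis
    # day found zero leaves
    leafless <- vapply(doys, function(d) {
      prior <- which(lc$doy <= d)
      length(prior) > 0 && lc$count[prior[which.max(lc$doy[prior])]] == 0L
    }, logical(1))

    gsw <- 0.02 + 0.015 * pmax(a_true, 0)
    artifact <- runif(nd) < config$qc_artifact_rate
    gsw[artifact] <- -runif(sum(artifact), 0.001, 0.05)

    covered <- rep(1, nd)
    small <- runif(nd) < config$small_leaf_rate & !leafless
    covered[small] <- runif(sum(small), 0.5, 0.95)
    a_rec <- a_obs * covered  # chamber-average reading for small leaves

    a_rec[leafless] <- 0
    gsw[leafless] <- 0
    covered[leafless] <- 1

    list(a_net = a_rec, covered = covered, gsw = gsw, leafless = leafless)
  })

  tibble::tibble(
    tree_id = rep(design$tree_id, each = nd),
    doy = rep(doys, nrow(design)),
    a_net = unlist(lapply(out, `[[`, "a_net")),
    covered_fraction = unlist(lapply(out, `[[`, "covered")),
    gsw = unlist(lapply(out, `[[`, "gsw")),
    leafless_flag = unlist(lapply(out, `[[`, "leafless"))
  )
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: generates the design for `config$seed` (unless one is
#' supplied) and all three observation tables, mutually consistent at the
#' tree level.
#'
#' @param config A [sim_config()].
#' @param design Optional design tibble; defaults to
#'   `generate_design(config$seed)`.
#' @return A named list with tibbles `trees`, `counts`, `spad`,
#'   `photosynthesis`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 1))
#' names(sim)
simulate_experiment <- function(config, design = NULL) {
  validate_sim_config(config)
  if (is.null(design)) design <- generate_design(config$seed)
  list(
    trees = design,
    counts = simulate_counts(design, config),
    spad = simulate_chlorophyll(design, config),
    photosynthesis = simulate_photosynthesis(design, config)
  )
}
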