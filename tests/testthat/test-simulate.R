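design <- generate_design(seed = 2)

test_that("sim_config validates its schedules and parameters", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(photosynthesis_doys = c(240, 258)),
               "6 strictly increasing")
  expect_error(sim_config(counts_spad_doys = 1:12), "13 strictly increasing")
  expect_error(sim_config(event_doys = list(leaf_removal_1 = 225,
                                            bud_removal = 216,
                                            leaf_removal_2 = 163)),
               "ordered")
  expect_error(sim_config(spad_sd = -1), ">= 0")
  expect_error(sim_config(qc_artifact_rate = 1.5), "\\[0, 1\\]")
})

test_that("removal remainder uses round-half-to-even at ties", {
  rem <- phenosink:::removal_remainder
  expect_equal(rem(40, 75), 10)
  expect_equal(rem(40, 0), 40)
  expect_equal(rem(10, 75), 2)  # 2.5 rounds to even 2
  expect_equal(rem(2, 25), 2)   # 1.5 rounds to even 2
  expect_equal(rem(6, 25), 4)   # 4.5 rounds to even 4
})

test_that("counts honour the removal arithmetic at every event", {
  counts <- simulate_counts(design, nf_config())
  wide <- tidyr::pivot_wider(
    counts[counts$event_phase != "none", ],
    names_from = "event_phase", values_from = "count"
  )
  d <- dplyr::left_join(wide, design, by = "tree_id")
  pct <- ifelse(d$organ == "leaf", d$leaf_removal_pct, d$bud_removal_pct)
  expect_equal(d$post, round((1 - pct / 100) * d$pre))
  # untreated organs show no discontinuity at the events, even with noise
  noisy <- simulate_counts(design, sim_config(seed = 7))
  nz <- tidyr::pivot_wider(noisy[noisy$event_phase != "none", ],
                           names_from = "event_phase", values_from = "count")
  nz <- dplyr::left_join(nz, design, by = "tree_id")
  untreated <- ifelse(nz$organ == "leaf", nz$leaf_removal_pct,
                      nz$bud_removal_pct) == 0
  expect_equal(nz$post[untreated], nz$pre[untreated])
})

test_that("expected regrowth before the second removal grows with the removed fraction", {
  cfg <- nf_config()
  counts <- simulate_counts(design, cfg)
  leaf_ev <- counts[counts$organ == "leaf" & counts$event_phase != "none", ]
  wide <- tidyr::pivot_wider(leaf_ev, names_from = "event_phase",
                             values_from = "count")
  wide <- dplyr::left_join(wide, design, by = "tree_id")
  e1 <- wide[wide$doy == cfg$event_doys$leaf_removal_1, ]
  e2 <- wide[wide$doy == cfg$event_doys$leaf_removal_2, ]
  gain <- setNames(e2$pre - e1$post[match(e2$tree_id, e1$tree_id)],
                   e2$tree_id)
  mean_gain <- tapply(gain, design$treatment[match(names(gain),
                                                   design$tree_id)], mean)
  expect_gt(mean_gain[["leaf_75"]], mean_gain[["leaf_50"]])
  expect_gt(mean_gain[["leaf_50"]], mean_gain[["leaf_25"]])
  expect_equal(unname(mean_gain[["control"]]), 0)
  # deterministic regrowth equals the rounded expectation
  expect_equal(unname(gain),
               round(cfg$regrowth_gain *
                       (e1$pre - e1$post)[match(names(gain), e1$tree_id)]))
})

test_that("noise-free SPAD follows the logistic with the configured delay", {
  cfg <- nf_config()
  spad <- simulate_chlorophyll(design, cfg)
  # interpolated day at which SPAD halves, per tree
  half_day <- vapply(split(spad, spad$tree_id), function(s) {
    s <- s[order(s$doy), ]
    i <- max(which(s$avg_spad >= cfg$spad_plateau / 2))
    with(s, doy[i] + (avg_spad[i] - cfg$spad_plateau / 2) /
           (avg_spad[i] - avg_spad[i + 1]) * (doy[i + 1] - doy[i]))
  }, numeric(1))
  trt <- design$treatment[match(names(half_day), design$tree_id)]
  delay75 <- mean(half_day[trt == "leaf_75"]) -
    mean(half_day[trt == "control"])
  expect_equal(delay75, 75 * cfg$true_senescence_delay_per_pct,
               tolerance = 0.2 / 4.31)
  # bud removal is a true null by default
  delay_bud <- mean(half_day[trt == "bud_75"]) -
    mean(half_day[trt == "control"])
  expect_lt(abs(delay_bud), 0.1)
})

test_that("SPAD values are non-negative and plateau early in the season", {
  spad <- simulate_chlorophyll(design, sim_config(seed = 3))
  expect_true(all(spad$avg_spad >= 0))
  early <- spad$avg_spad[spad$doy == min(spad$doy)]
  expect_equal(mean(early), 40, tolerance = 0.05)
})

test_that("noise-free photosynthesis AUC ratio equals the configured effect exactly", {
  cfg <- nf_config()
  sim <- simulate_experiment(cfg, design)
  met <- tree_metrics(sim, cfg)
  r <- mean(met$total_autumn_photo[met$treatment == "leaf_75"]) /
    mean(met$total_autumn_photo[met$treatment == "control"])
  expect_equal(r, 1 + cfg$true_photo_effect_pct / 100, tolerance = 1e-8)
})

test_that("photosynthesis artifacts and small leaves occur at plausible rates", {
  cfg <- sim_config(seed = 5)
  photo <- simulate_photosynthesis(design, cfg)
  expect_equal(nrow(photo), 81 * 6)
  n_active <- sum(!photo$leafless_flag)
  n_artifact <- sum(photo$gsw < 0)
  expect_gt(n_artifact, 0.01 * n_active)
  expect_lt(n_artifact, 0.12 * n_active)
  small <- photo$covered_fraction < 1
  expect_true(all(photo$covered_fraction[small] >= 0.5))
  expect_gt(sum(small), 0.05 * n_active)
  expect_lt(sum(small), 0.30 * n_active)
  # leafless records are true zeros
  lf <- photo[photo$leafless_flag, ]
  expect_true(all(lf$a_net == 0 & lf$gsw == 0 & lf$covered_fraction == 1))
})

test_that("the generator is deterministic and subset-consistent", {
  cfg <- sim_config(seed = 9)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_experiment(sim_config(seed = 10))
  expect_false(identical(s1$spad$avg_spad, s3$spad$avg_spad))
  # simulating a subset of trees reproduces the full table's rows exactly
  sub <- design[c(5, 20, 60), ]
  full_counts <- simulate_counts(design, cfg)
  sub_counts <- simulate_counts(sub, cfg)
  expect_identical(sub_counts,
                   full_counts[full_counts$tree_id %in% sub$tree_id, ])
  full_photo <- simulate_photosynthesis(design, cfg)
  sub_photo <- simulate_photosynthesis(sub, cfg)
  expect_identical(as.data.frame(sub_photo),
                   as.data.frame(full_photo[full_photo$tree_id %in%
                                              sub$tree_id, ]))
})

test_that("noise_free zeroes every stochastic element", {
  cfg <- noise_free(sim_config(seed = 1))
  for (p in c("leaf_count_sd", "bud_count_sd", "count_sd", "spad_sd",
              "photo_sd", "tree_sd", "block_sd", "photo_tree_cv",
              "qc_artifact_rate", "small_leaf_rate"))
    expect_equal(cfg[[p]], 0)
  photo <- simulate_photosynthesis(design, cfg)
  expect_true(all(photo$gsw >= 0))
  expect_true(all(photo$covered_fraction == 1))
})
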