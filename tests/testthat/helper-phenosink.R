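# Shared fixtures and independent oracles.

# a config with every stochastic element switched off
nf_config <- function(seed = 1, ...) {
  cfg <- noise_free(sim_config(seed = seed))
  modifyList(cfg, list(...))
}

# independent brute-force oracle for the last upward threshold crossing:
# scan every adjacent pair, collect all crossings, interpolate in the last
oracle_last_crossing <- function(doy, v, thr = 0.5) {
  hits <- c()
  for (i in seq_len(length(v) - 1)) {
    if (v[i] < thr && v[i + 1] >= thr) hits <- c(hits, i)
  }
  if (length(hits) == 0) return(NA_real_)
  i <- hits[length(hits)]
  doy[i] + (thr - v[i]) / (v[i + 1] - v[i]) * (doy[i + 1] - doy[i])
}

# random monotone-with-noise senescence-like series in [0, 1]
random_index_series <- function(n = 9) {
  doy <- sort(sample(200:340, n))
  base <- plogis((doy - runif(1, 250, 320)) / runif(1, 3, 15))
  v <- pmin(1, pmax(0, base + rnorm(n, 0, 0.08)))
  list(doy = doy, v = v)
}

# small synthetic mixed-model dataset with known structure
lmm_test_data <- function(n_block = 8, per_block = 6, beta_leaf = 0.1,
                          beta_bud = 0, block_sd = 1, resid_sd = 1,
                          seed = 1) {
  set.seed(seed)
  n <- n_block * per_block
  d <- data.frame(
    block_id = rep(seq_len(n_block), each = per_block),
    leaf_removal_pct = sample(c(0, 25, 50, 75), n, replace = TRUE),
    bud_removal_pct = sample(c(0, 25, 50, 75), n, replace = TRUE)
  )
  blk <- rnorm(n_block, 0, block_sd)
  d$y <- 10 + beta_leaf * d$leaf_removal_pct + beta_bud * d$bud_removal_pct +
    blk[d$block_id] + rnorm(n, 0, resid_sd)
  d
}
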