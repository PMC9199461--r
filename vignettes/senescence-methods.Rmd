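---
title: "Methods: senescence metrics, QC and inference in phenosink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: senescence metrics, QC and inference in phenosink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosink)
```

## The experiment being modelled

`phenosink` analyses a randomized-block carbon source--sink manipulation
experiment on deciduous saplings. Eighty-one trees receive one of eight
treatments — leaf removal at 25/50/75%, bud removal at 25/50/75%, a combined
50% leaf + 50% bud removal, or untreated control (eleven controls, ten trees
per other treatment) — laid out in ten blocks, with five spring leaf-out
groups balanced across treatments. Leaves are removed twice (day of year
163 and 225, the second removal also taking back compensatory regrowth);
buds once (DOY 216). Through autumn the crews record:

* thirteen count/SPAD campaigns (DOY 228–330): full leaf and bud counts
  (censuses, not estimates) and the average SPAD chlorophyll reading;
* six gas-exchange campaigns (first days DOY 240–330): leaf-level net
  photosynthesis `a_net`, stomatal conductance `gsw`, and the fraction of
  the chamber covered by the leaf.

The two scientific questions are whether reducing the carbon *source*
(leaves) delays autumn senescence and raises the remaining leaves'
photosynthesis, and whether reducing the *sink* (buds) does the opposite.

## Derived metrics

**Inverted relative SPAD index** (`inverted_spad_index()`). For tree $i$ at
date $d$ with leaf count $LC$ and average SPAD $Chl$:

$$\mathrm{index}_i(d) \;=\; \left| \frac{LC_i(d)\,Chl_i(d)}
 {\max_t \, LC_i(t)\,Chl_i(t)} \;-\; 1 \right| \in [0, 1],$$

0 at the tree's greenest date and 1 once all leaves are shed. The
normalising maximum is taken over the tree's *full* measurement series,
before any window restriction, so restricting the modeling window never
changes individual index values (tested as a scale-invariance and
window-consistency property).

**Modeling window** (`restrict_to_modeling_window()`). Senescence modeling
uses campaigns at or after DOY 274 (30 September), keeping the last 9 of
the 13 campaigns — the early campaigns only anchor the index maximum.

**DOY of 50% senescence** (`doy_50pct_senescence()`). The *last* adjacent
pair of points with $v_1 < 0.5 \le v_2$ is linearly interpolated; a point
exactly at threshold is its own crossing; a series that never reaches the
threshold yields `NA` and is flagged (`doy_50pct_defined = FALSE`), never
silently dropped inside the metric. Taking the last crossing makes the
estimate robust to transient early dips above threshold from noise. The
implementation is tested against a brute-force crossing enumerator on
1,000 random series.

**Total autumn photosynthesis** (`total_autumn_photosynthesis()`).
Trapezoidal area under the QC-cleaned `a_net` series with time in *days*:
units are µmol m⁻² s⁻¹ · day. We deliberately do not multiply by 86,400
s/day: every comparison in the pipeline is a ratio or difference of AUCs on
the same time base, so the constant cancels; keeping rates in their native
per-second units avoids a silent unit conversion in the data tables.

**Total relative carbon gain** (`total_relative_carbon_gain()`). Each rate
is scaled by (temporally closest leaf count) / (pre-treatment leaf count)
before integration — equidistant ties resolve to the earlier count — giving
a whole-tree, defoliation-aware integral.

## Quality control

`qc_photosynthesis()` applies four steps in a fixed, documented order:

1. `assign_interval_day()`: measurements taken over a multi-day campaign
   are assigned to the campaign's first day; a record outside every
   interval is an error naming the tree and day.
2. `correct_leaf_area()`: chamber-average rates from leaves that do not
   fill the chamber are divided by the covered fraction (done *before* any
   sign-based rule, so a small negative reading is corrected, not masked).
3. `screen_plausibility()`: rule predicates drop impossible records; the
   single documented default is negative stomatal conductance.
4. `resolve_nonpositive()`: leafless trees record true zeros (`zeroed`);
   a negative rate is zeroed when it is biologically a season-end zero
   (final interval, or the tree is leafless by the next interval) and
   dropped otherwise.

Every record ends in exactly one of `kept` / `zeroed` / `dropped`; dropped
rows stay in the table, so record counts are conserved and the full chain
is idempotent — re-running QC on its own output is a no-op. Both properties
are enforced by tests.

## Inference

Endpoint models (one row per tree) put the removal percentages in as
*continuous* covariates with their interaction, and a random intercept per
block:

```
response ~ leaf_removal_pct + bud_removal_pct +
           leaf_removal_pct:bud_removal_pct + (1 | block_id)
```

* **Fitting**: REML via `lmerTest::lmer()` with Satterthwaite degrees of
  freedom (`fit_lmm()`). A `boundary (singular)` fit is reported as a valid
  solution with `singular = TRUE`; only genuine optimizer failures unset
  `converged`. (Treating singular fits as failures would selectively drop
  replicates whose block variance is estimated at zero and bias recovery
  studies.)
* **Term tests**: Type-II Wald chi-square via `car::Anova()`
  (`effect_tests()`); each continuous covariate has 1 df.
* **Model reduction** (`prune_interactions()`): highest-order interactions
  are tested first; the least significant non-significant interaction is
  removed and the model refitted until all remaining interactions are
  significant at α = 0.05. Main effects are never pruned.
* **R²** (`r2_mixed()`): variance-decomposition marginal and conditional
  R² — fixed-effect prediction variance over the total of fixed, random
  and residual variances. Hand-implemented in a few lines over the
  `lme4::VarCorr()` components and cross-checked against constructed
  variance shares in the tests.
* **Uncertainty** (`bootstrap_ci()`): model-based *parametric* bootstrap
  via `lme4::bootMer()` — simulate from the fitted model, refit, collect
  population-level predictions; the interval is the point prediction
  ± 1.96 bootstrap SDs. Failed refits are counted and more than 10%
  failures is an error, not a silent narrowing.

Responses that require it can be fitted on the log or square-root scale
(`model_spec(transform = )`); predictions are back-transformed.

## The synthetic-experiment generator

Because the original raw data are unreleased, the package generates
synthetic experiments whose *truths are known*, so the whole pipeline can
be validated by parameter recovery rather than by comparison to fixed
numbers.

Latent state per tree: initial leaf/bud counts, a senescence-midpoint shift
(block + tree Gaussian effects plus the treatment effect), and a
multiplicative photosynthesis amplitude factor. All per-tree randomness is
keyed by a deterministic hash of (seed, tree id, purpose), so the counts,
SPAD and photosynthesis tables of one tree are mutually consistent
regardless of the order, or subset of trees, in which they are generated.

Observation models:

* **Counts**: removals take `round((1 - pct/100) * count)` (round-half-to-
  even at ties); between events a removed organ regrows an expected
  `regrowth_gain` fraction of its deficit (Poisson, or its deterministic
  expectation when `count_sd = 0`); late-season leaf counts decline along
  a lagged, steeper abscission logistic.
* **SPAD**: plateau times a declining logistic in time, whose midpoint is
  shifted by `true_senescence_delay_per_pct` days per percent of leaves
  removed — the simulation truth targeted by the senescence models.
* **Photosynthesis**: a seasonal logistic whose amplitude is scaled so the
  noise-free AUC at 75% leaf removal exceeds control by exactly
  `true_photo_effect_pct` percent (linear in the removal percentage). QC
  exercise is built in: a configurable fraction of records gets a negative
  conductance artifact or a chamber-underfilling leaf, and trees that have
  shed all leaves record zeros.

Key default parameters and their rationale:

| parameter | default | units | rationale |
|---|---|---|---|
| `true_senescence_delay_per_pct` | 4.31/75 ≈ 0.0575 | d per % | target effect; 75 × slope = 4.31 d at 75% removal |
| `true_senescence_delay_per_pct_bud` | 0 | d per % | the bud arm is a true null by default |
| `true_photo_effect_pct` | 14 | % | target AUC effect at 75% removal |
| `regrowth_gain` | 0.5 | — | half the deficit regrown between events |
| `senescence_midpoint_doy` | 300 | DOY | senescence is barely under way at the DOY-274 window start; an earlier midpoint left-censors early-senescing controls and biases the recovered slope |
| `senescence_steepness` | 8 | d | chlorophyll decline over ~1 month |
| `leaf_fall_lag`, `leaf_fall_steepness` | 15, 5 | d | abscission lags chlorophyll loss and is steeper, keeping trees foliated through the last campaign in the noise-free limit |
| `photo_midpoint_doy`, `photo_steepness` | 280, 9 | DOY, d | gas exchange ≈ 0 by the final campaigns |
| `leaf_count_mean`, `leaf_count_sd` | 600, 100 | leaves | sapling-scale censuses; with far smaller counts, integer rounding clips the index's normalising maximum for heavily defoliated trees (a ~10-leaf tree cannot round above its post-removal count), which measurably delays their 0.5 crossing and biases the recovered slope upward |
| `count_sd` | 0 | leaves | counts are complete censuses; nonzero count noise is a sensitivity knob only — it inflates each tree's index-normalising maximum in proportion to sd/count, far more for 75%-removal trees, and so introduces a treatment-correlated bias |
| `spad_sd`, `photo_sd` | 2, 0.5 | SPAD, µmol m⁻² s⁻¹ | instrument-scale noise |
| `tree_sd`, `block_sd` | 12, 2 | d | phenological spread between trees and blocks, calibrated so the endpoint model's slope standard error matches the motivating study's reported uncertainty; tree shifts are truncated at ±2 SD because the campaign calendar brackets the cohort's senescence — unbounded tails leave occasional trees green past the final campaign, and the selective loss of their (censored) crossing days biases the treatment contrast |
| `qc_artifact_rate`, `small_leaf_rate` | 0.05, 0.15 | — | exercise the QC rules at realistic rates |

What the generator does **not** emulate: weather-driven year effects,
within-campaign measurement-day spread (all records sit on campaign first
days), spatial autocorrelation beyond the block intercept, and senescence
trajectories that depart from a single logistic. It is a validation
instrument for the estimators, not an ecological forecast model.

`noise_free(cfg)` zeroes every stochastic element; in that limit the
pipeline recovers the configured truths exactly (the AUC ratio to machine
precision; the delay up to interpolation on the weekly campaign grid), and
these invariants are tested.

## Parameter recovery

`recovery_study()` repeats simulate → QC → metrics → fit over independent
replicates of the full 81-tree design and summarises the recovered
senescence slope (and its implied 75%-removal delay), the percent AUC
difference between 75% removal and control, and optionally the empirical
coverage of the parametric bootstrap intervals. Replicate seeds are drawn
below 2³¹ from the master seed, so a study is fully reproducible from one
integer.

Problem sizes and indicative timings (single CPU): one 81-tree experiment
simulates in well under a second; a full pruned endpoint fit takes ~0.2 s;
a 200-replicate recovery study runs in about a minute; 1,000 bootstrap
refits of an endpoint model take ~10 s.

## Limitations

* The endpoint models treat removal percentages as linear gradients, as in
  the motivating design; strong curvature in a real dose–response would be
  attributed to the linear term.
* The DOY of 50% senescence is undefined for trees that never cross the
  threshold inside the window; such trees are flagged and excluded from the
  endpoint model rather than imputed.
* Bootstrap intervals are normal-theory (± 1.96 SD) rather than percentile
  intervals, matching the small per-fit simulation budgets used here.
* The generator's truths are effects *built into* the latent logistics; it
  validates estimator correctness, not the biological claims themselves.
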