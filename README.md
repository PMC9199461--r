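# phenosink

Analysis pipeline for randomized-block carbon source–sink manipulation
(defoliation/debudding) experiments on deciduous saplings — and a
synthetic-experiment generator with known truths so the whole pipeline can
be validated by parameter recovery.

## The science

Autumn leaf senescence is hypothesised to be driven in part by carbon
sink limitation: if a tree's sinks fill up, its leaves shut down sooner.
The experiment the package models manipulates the source–sink balance of
81 saplings across eight treatments — leaf removal at 25/50/75% (less
source), bud removal at 25/50/75% (less sink), a combined 50%/50%
removal, and untreated control — in ten blocks, and follows autumn
senescence and leaf gas exchange through thirteen count/SPAD campaigns and
six photosynthesis campaigns. The core quantities:

* **Inverted relative SPAD index** — per tree and date,
  `index(d) = | LC(d)·Chl(d) / max_t(LC(t)·Chl(t)) − 1 |`, a whole-crown
  senescence score in [0, 1] combining leaf count and chlorophyll.
* **DOY of 50% senescence** — the day of year at which the index crosses
  0.5, linearly interpolated at the *last* upward crossing, within a
  modeling window starting DOY 274 (30 September).
* **Total autumn photosynthesis** — trapezoidal area under the QC-cleaned
  net photosynthesis series (µmol m⁻² s⁻¹ · day), plus a leaf-count-scaled
  *relative carbon gain* variant.
* **Mixed-model inference** — removal percentages as continuous covariates
  with block random intercepts, REML + Satterthwaite df, Type-II Wald
  chi-square tests, interaction pruning at α = 0.05,
  marginal/conditional R², and model-based parametric bootstrap CIs.

The expected findings (and the generator's default truths): leaf removal
*delays* senescence by about 0.06 d per percent removed (≈ 4.3 days at
75%) and raises the remaining leaves' integrated photosynthesis by ~14%
at 75% removal; bud removal does neither (a true null).

See the methods vignette (`vignettes/senescence-methods.Rmd`) for the
full model, QC rules, generator design and limitations.

## Worked example

Simulate one experiment, clean it, derive per-tree metrics, and fit the
senescence endpoint model:

```r
library(phenosink)

cfg <- sim_config(seed = 1)
cfg
#> <sim_config>
#>   seed: 1
#>   events (DOY): leaf 163 | bud 216 | leaf 225
#>   schedules: 6 photosynthesis + 13 count/SPAD campaigns
#>   truths: delay 0.05747 d/% leaf; photo effect 14 % at 75%

sim <- simulate_experiment(cfg)
qc  <- qc_photosynthesis(sim$photosynthesis,
                         measurement_schedule(cfg$photosynthesis_doys))
table(qc$observations$qc_status)
#> dropped    kept  zeroed
#>      55     397      34

sim$photosynthesis <- qc$observations
met <- tree_metrics(sim, cfg)
head(met[, c("tree_id", "treatment", "total_autumn_photo", "doy_50pct")], 4)
#>   tree_id treatment total_autumn_photo doy_50pct
#> 1 T01     control                 156.      310.
#> 2 T02     control                 206.      295.
#> 3 T03     control                 346.      294.
#> 4 T04     control                 341.      311.

pr <- prune_interactions(model_spec("doy_50pct"), met)
pr$log
#>   term                                  p action
#> 1 leaf_removal_pct:bud_removal_pct 0.0933 dropped
pr$fit
#> <pheno_fit> doy_50pct, n = 81
#>               term  estimate      se    df         p
#> 1      (Intercept) 2.999e+02 2.16158 43.15 7.976e-59
#> 2 leaf_removal_pct 1.218e-01 0.04074 69.10 3.880e-03
#> 3  bud_removal_pct 6.243e-03 0.04074 69.10 8.787e-01
#>   R2 marginal 0.104 / conditional 0.175

bootstrap_ci(pr$fit,
             data.frame(leaf_removal_pct = c(0, 75), bud_removal_pct = 0),
             n_sim = 500, seed = 1)
#>   leaf_removal_pct bud_removal_pct      fit  se_boot  lower95  upper95
#> 1                0               0 299.8883 2.175082 295.6252 304.1515
#> 2               75               0 309.0201 2.275022 304.5610 313.4791
```

A single replicate is noisy — this one recovers a slope of 0.122 d/%
against a truth of 0.057. Averaging over replicates is what validates the
estimator:

```r
rs <- recovery_study(sim_config(), n_reps = 200, seed = 1)
rs
#> <recovery_study> 200 replicates (200 converged fits)
#>   senescence delay slope: truth 0.0575, recovered 0.0572 +/- 0.0035 (MC SE)
#>   implied 75% delay: 4.29 days +/- 0.26
#>   photosynthesis effect: truth 14.0%, recovered 14.09% +/- 0.71
```

`run_pipeline(run_config(seed = 1), out_dir = "out")` runs the whole
chain (simulate → QC → metrics → three endpoint fits → bootstrap
prediction grid) and writes CSVs plus a manifest with file checksums;
identical configurations produce byte-identical outputs. A thin shell
wrapper over the same API lives at `inst/cli/phenosink.R`
(`simulate | qc | metrics | fit | run | recover` verbs).

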