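# sncvigor

Analysis pipeline for studying how substantia nigra pars compacta (SNc)
dopaminergic neurons relate to the *vigor* of single-forelimb movement
sequences. Mice press a lever with one forelimb under an FR4/1-s schedule
(four presses in under one second earn a sucrose reward) while SNc
activity is imaged at 10 Hz with a GCaMP6f miniscope; each forelimb is
tested in its own daily session, so every neuron is observed in a
contralateral and an ipsilateral condition. Unilateral striatal 6-OHDA
provides the causal counterpart on the behavioral side.

The package is aimed at systems-neuroscience users who have extracted
fluorescence traces (e.g., with CNMF-E) and behavioral event logs and want
a tested, reproducible implementation of the downstream analysis:

* **Sequence segmentation** — bouts of presses gated by snout-ROI
  occupancy; reward-rule logic (`target_ipi(4, 1)` = 0.333 s); session
  metrics including the inter-press-interval Fano factor.
* **Event-aligned classification** — PETHs from -8 to +6 s in 0.1 s bins;
  a neuron is modulated when ≥ 2 consecutive bins of the trial-averaged
  PETH exceed the 99th percentile of its -8 to -3 s baseline bins.
  Windows: movement initiation (-2, 0) s around the first press; reward
  (0, 1) s after the first rewarded lick (and silent before it); magazine
  approach (-2, 0) s before the lick; execution (0, 1) s after the press.
* **Cross-session ROI matching** — mutual-nearest-centroid matching
  (≤ 5 px), and functional stability via max-event Spearman correlations
  of (-10, +6) s PETHs against time-shuffled and different-ROI controls,
  Fisher-Z averaged.
* **Population statistics** — per-mouse paired proportions, pooled
  neuron-level pooled-variance t contrasts of peak pre-press activity,
  Spearman length-coding of per-bout peaks on the ordinal length groups
  (≤2, 3, 4, 5, 6, 7+), the post hoc linear-trend F, Fisher's exact
  contrast of length-modulated proportions, and a hypergeometric
  overlap-vs-chance test of the movement and reward populations.
* **Lesion contrast** — per mouse x epoch x forelimb mean
  presses/sequence and % long sequences (strictly above the pre-treatment
  mean), 2x2 repeated-measures ANOVA with Sidak post hocs, after/before
  ratios, paired and one-sample ratio tests.
* **Synthetic data** — `sim_config()` + `simulate_behavior()` +
  `simulate_traces()` generate the full study design (6 mice, 3 days,
  2 sessions/day, ~17 neurons/mouse) with planted classes, lateralized
  amplitudes, contralateral-only length gain and the lesion effect, so the
  entire pipeline runs and is validated without any recordings.

## Worked example

Simulate a small two-mouse cohort and run every stage:

```r
library(sncvigor)
cfg <- sim_config(seed = 7, n_mice = 2, n_days = 2, session_duration = 600,
                  max_rewards = 15L, n_neurons_per_mouse = 8L)
res <- run_pipeline(cfg)

mt <- subset(res$modtable, condition == "contra")
cat(sprintf("neurons: %d | movement %.0f%% | reward %.0f%% | magazine %.0f%%\n",
            nrow(mt), 100*mean(mt$is_movement), 100*mean(mt$is_reward),
            100*mean(mt$is_magazine)))
#> neurons: 16 | movement 44% | reward 31% | magazine 6%

res$population$amplitude_test    # contra vs ipsi peak pre-press activity
#> t_unpaired: statistic = 7.8, df = 12, p = 4.865e-06 (positive)

res$population$overlap           # movement/reward overlap vs chance
#> overlap_chance: statistic = 1, df = NA, p = 0.3077 (negative)

res$matching$summary             # cross-day ROI tracking
#> # A tibble: 1 x 3
#>   n_tracked n_full pct_full
#> 1        16     16      100
```

The movement fraction and the significant contralateral amplitude
advantage recover the planted generator settings (44% recovered vs 39%
planted at n = 16; amplitudes 0.646 vs 0.427 z); the movement/reward
overlap is consistent with independent allocation, as planted.

The lesion arm uses the bout-level generator and the repeated-measures
machinery:

```r
b <- simulate_lesion_bouts(sim_config(seed = 7), "6OHDA")
lesion_stats(b)[["6OHDA"]]$anova_length
#> 2x2 repeated-measures ANOVA (n = 8 subjects)
#>         factor         F df_num df_den            p
#> 1        epoch 51.585408      1      7 0.0001802102
#> 2         limb  5.342115      1      7 0.0540829946
#> 3 epoch_x_limb 27.135401      1      7 0.0012404605
#> post hoc (Sidak-adjusted paired contrasts):
#>    level   mean_1   mean_2         t df            p     p_sidak
#> 1 contra 4.196250 2.177188 -7.328604  7 0.0001588136 0.000317602
#> 2   ipsi  3.988437 3.424062 -3.386151  7 0.0116604620 0.023184958
```

The contralateral forelimb collapses from ~4.2 to ~2.2 presses/sequence
while the ipsilateral limb barely moves, producing the epoch x forelimb
interaction — the signature of a lateralized vigor deficit.

See `vignettes/snc-sequence-vigor.Rmd` for the models, parameter
conventions and the generator's design choices.

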