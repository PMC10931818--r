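---
title: "Analyzing lateralized nigral dopamine activity and sequence vigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing lateralized nigral dopamine activity and sequence vigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncvigor)
```

## The scientific problem

Dopaminergic neurons (DANs) of the substantia nigra pars compacta are
transiently active before self-initiated movements, and their loss produces
not only slower but also *shorter* movement sequences. `sncvigor`
implements the analysis chain needed to ask whether pre-movement DAN
activity is lateralized and scales with the length of the upcoming
sequence: mice press a lever with a single forelimb under a fixed-ratio-4
schedule with a 1 s completion window (FR4/1 s), while one hemisphere's
SNc is imaged at 10 Hz through a GRIN lens. Each forelimb is tested in its
own daily session, so every neuron is observed in a *contralateral* and an
*ipsilateral* condition.

The package has six analysis layers plus a simulator:

1. **Behavior** — parse event logs; segment presses into sequence bouts
   using snout-ROI occupancy; compute session metrics (press rates, IPI
   mean and Fano factor, percentage of presses in sequences).
2. **Neural events** — per-session z-scoring, peri-event time histograms
   (PETHs), a consecutive-bin percentile modulation test, and window-based
   classification into movement-initiation, execution, reward and
   magazine-approach neurons.
3. **ROI matching** — centroid-based cross-day matching with shuffled and
   different-ROI correlation controls.
4. **Population statistics** — laterality of proportions and peak
   amplitudes, sequence-length coding, overlap-vs-chance.
5. **Lesion contrast** — before/after x forelimb repeated-measures design
   for unilateral 6-OHDA vs saline.
6. **Statistics core** — the primitives behind all of the above, each
   validated against a brute-force oracle in the test suite.

## Sequence segmentation and the reward rule

A *sequence bout* is a maximal run of presses performed while the snout
occupies the lever-adjacent region of interest; an isolated press is a
bout of one. Presses covered by no occupancy interval are excluded as
orphans and counted (the occupancy signal can drop mid-bout; we flag
rather than guess). For logs without position data a configurable
inter-press-gap rule (default 2 s) is provided; the two definitions agree
on clean data and the occupancy rule is canonical.

The FR4/1-s rule rewards four consecutive presses spanning less than one
second, which fixes the target inter-press interval at
`target_ipi(4, 1)` = `r round(target_ipi(4, 1), 3)` s. Bout lengths are
summarized on an ordinal grid that pools 1-2 presses and 7-or-more
presses (`<=2, 3, 4, 5, 6, 7+`), because tail lengths are rare and their
cardinal spacing is not meaningful for rank statistics.

```{r segment-example}
log <- event_log("demo", lever_side = "left", hemisphere = "right",
                 press_times = c(10, 10.31, 10.62, 10.9, 25.0),
                 occupancy = rbind(c(9.5, 11.5), c(24.5, 25.5)),
                 session_duration = 60)
segment_sequences(log)[, c("n_presses", "start", "rewarded", "length_group", "limb")]
```

## PETHs and the modulation test

PETHs span -8 to +6 s around the aligned event in 0.1 s bins (140 bins),
with the event on a bin edge and left-closed bins. Bins from -8 to -3 s
form the baseline. A neuron is *positively modulated* in a test window
when at least two consecutive bins of its trial-averaged PETH exceed the
99th percentile of the baseline bins; negative modulation uses the 1st
percentile symmetrically. We read "a threshold of 99% above the baseline"
distributionally — the 99th percentile of the baseline-bin distribution of
the mean PETH — since only that reading turns the preceding definition of
baseline *distributions* into a usable threshold. The baseline
distribution is taken over mean-PETH bins (not pooled per-trial bins); a
config switch in `classify_modulation()`'s arguments would accept any
alternative window.

Classification windows: movement initiation, (-2, 0) s before the first
press; execution, (0, +1) s after the first press (when bout context is
present the bout's own span can be substituted); reward, (0, +1) s after
the first rewarded lick *and* silent before it; magazine approach,
(-2, 0) s before the rewarded lick. Flags are kept separately — the same
neuron can carry a movement and a magazine flag — and a single exclusive
`class` label resolves them with movement taking precedence, which is the
label used for per-class population fractions. Peak activity is the
maximum of a centered 3-bin moving average, truncated (not dropped) at
window ends so the boundary bin still contributes. Two pre-press peak
windows coexist deliberately: 2 s for the laterality contrast and 1 s for
the per-bout length analyses of matched sessions; both are arguments.

The consecutive-bin rule is *not* an exact 1% test: with a finite (50-bin)
baseline the per-bin exceedance probability is above 1%, and the
two-in-a-row requirement brings the family rate back down (about 2% for
the 20-bin pre-press window). The acceptance suite therefore checks the
empirical null rate against an independent Monte-Carlo implementation of
the same rule rather than against a nominal constant.

## Cross-day matching and stability controls

ROI centroids are matched between sessions by mutual nearest neighbor with
a 5 px distance gate (at the binned resolution). The gate plus mutuality
is our reproducible surrogate for the visual shape inspection a human
would perform on the top candidates; the three nearest candidates are
retained for audit. Multi-session tracks are assembled from pairwise
matches in ascending distance, never putting two same-session ROIs in one
track.

Functional stability uses a wider (-10, +6) s PETH window (the window
convention for correlation differs from the classification window on
purpose, mirroring the analysis it reproduces). For each matched pair the
Spearman correlation is computed per shared event (first press and
rewarded lick x contra/ipsi) and the maximum is kept; track-level values
average pairwise maxima through Fisher's Z. Controls: *shuffled* — the
matched PETH rotated circularly in time by at least 1 s (rotation, not
permutation, preserves autocorrelation; a permutation control would be
trivially easy to beat); *different* — the best non-matched ROI of the
same animal. A repeated-measures one-way ANOVA on z-transformed values
with Tukey contrasts summarizes the three groups.

## Sequence-length coding

For each movement-modulated neuron the per-bout peak pre-press activity is
correlated with the ordinal length group of that bout (Spearman, ranks
1-6). The neuron is *length-modulated* when rho > 0 at two-sided p < 0.05
(the direction of the sidedness is not stated in the source analysis; we
use the two-sided p with a positive-rho gate). The cohort-level trend test
is the post hoc linear contrast with equally spaced coefficients after a
one-way ANOVA on the neuron x length-group matrix of mean peaks —
trial-level correlations classify single neurons, the group-mean matrix
feeds the trend, matching the split between the two source analyses.

## Lesion contrast

Per mouse and forelimb, the mean presses/sequence and the percentage of
*long* sequences (strictly above that mouse-forelimb's pre-treatment mean;
strict, because the threshold is a non-integer mean and equality should
not count as "longer") are computed per epoch. Each measure enters a 2x2
within-subject ANOVA (epoch x forelimb) with Sidak-corrected per-forelimb
paired contrasts, plus after/before ratios (ratio of the mouse's own cell
means, not a mean of bout-level ratios), a paired t of contra vs ipsi
ratios and one-sample t tests of each ratio against 1. For a 2x2 fully
within design every F equals the squared paired t of the corresponding
subject-level contrast, which is how `rm_anova_2x2()` computes them; the
test suite verifies the equality with `aov()` error strata to 1e-8.

## Statistics core conventions

* Two-sided p-values throughout; sample (n-1) variances; pooled-variance
  (not Welch) unpaired t tests — the classical default, and the source
  analyses give no indication of a Welch correction.
* Spearman: mid-ranks for ties; exact permutation p by full enumeration
  when n <= 8 (40320 permutations), t approximation above.
* Fisher's exact test and the overlap test sum hypergeometric
  probabilities of outcomes no more probable than the observed one.
* Fisher-Z averaging clips |r| = 1 inputs to 1 - 1e-6 with a warning.
* Degenerate inputs (zero variance, empty classes, incomplete design
  cells) are flagged and excluded, never silently imputed.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions: 6 imaged mice, 3
performance days with one session per forelimb per day, sessions capped at
30 rewards or 30 min, ~4 bouts/min, truncated-Poisson bout lengths (support
1-12) with mean 4, log-normal IPIs (median 0.28 s, sigma 0.5), ~17
neurons/mouse (~102 total), class probabilities 0.39 movement / 0.37
reward / 0.15 magazine, GCaMP6f-like kernel (0.08 s rise, 0.4 s decay —
literature-typical constants, they only shape transients), unit-SD white
noise, 1 px centroid jitter. The lesion arm plants 8 treated and 6 control
mice with the observed cell means (contra 4.12 to 2.17, ipsi 4.13 to 3.52;
saline 3.40 to 2.73 / 3.06 to 2.46 — the control arm deliberately carries
the small shared time decline seen in the data, with the pure null one
override away) and a between-mouse SD of 0.57 derived from the reported
within-subject statistics.

Design choices that deserve justification:

* **Amplitudes are specified on the measurement scale.** The planted
  movement amplitudes (0.646 z contra, 0.427 z ipsi) are the values the
  *analysis* should recover as mean-PETH peaks. Because each trial's
  transient is jittered uniformly in (-1.5, -0.3) s before the first
  press, trial averaging attenuates the peak; the generator divides the
  per-trial amplitude by the numerically computed attenuation of the
  kernel under that jitter, evaluated on the imaging sample grid.
* **Length coding** is implemented as pre-press amplitude scaling for a
  configurable fraction (0.7) of contralateral movement neurons, centered
  on the modal 4-press group so the planted mean amplitude is preserved.
* **Reward and magazine membership are mutually exclusive** (one uniform
  draw) and independent of movement membership, keeping the
  movement x reward overlap calibrated to chance by construction.
* **Magazine approach** is modeled as a 1 s linear ramp ending at the
  rewarded lick; the reward-to-lick latency is log-normal with median
  ~1.8 s, a realistic magazine-approach time in these boxes. Both
  constants matter: they keep press-locked transients outside the
  pre-lick window, as in the real data where the movement and magazine
  classes are nearly disjoint.
* **Reward rate.** Under i.i.d. log-normal IPIs the strict 4-in-under-1-s
  rule cannot produce both a ~0.35 s mean IPI and a ~60% rewarded-bout
  rate; the defaults favor the IPI scale and yield ~45% rewarded bouts.
  Downstream analyses only consume reward *events*, so this compression
  affects trial counts, not effect sizes.
* **Same-class neurons share a response template** (class, side amplitude,
  kernel). One consequence: in the simulated field of view the best
  *different*-ROI correlation can exceed the matched one, because another
  neuron of the same class is an almost perfect functional twin. Real
  neurons have idiosyncratic latencies and mixed selectivity; the
  stability-ordering property (matched > different > shuffled) is
  therefore validated on `simulate_stable_peths()`, whose per-ROI
  templates are idiosyncratic, while the end-to-end pipeline reports its
  matching accuracy against ground-truth identity.

What passing tests on this generator do **not** show: robustness to
slow drift and neuropil contamination in real fluorescence, to
source-extraction cross-talk, to non-stationary behavior within a
session, or to occupancy-signal dropouts beyond the orphan-flagging
policy.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
default cohort (36 sessions, ~100 neurons; about a minute), the null
classifier calibration on 1e5 exchangeable PETHs, power analyses at the
reported ns (37/33 neurons, 8 treated mice) over 200-1000 replicates, and
matching fidelity over 500 replicate fields of view. Exact-enumeration
oracles run at n = 5 (Spearman) and totals <= 40 (Fisher). Tolerances:
oracle equivalences at 1e-8; Monte-Carlo comparisons at 2-3 binomial SEs.
Ties in centroid matching are resolved by ascending distance; bin edges
are half-open on the left; all seeds flow from a single integer.

## Known limitations

* Neuron-level tests pool neurons across mice (matching the reported
  degrees of freedom); mouse identity is retained in outputs but no
  hierarchical model is fitted.
* Press velocity is accepted as a precomputed per-press column only;
  inertial-sensor processing and video tracking are out of scope, as are
  CNMF-E source extraction and motion correction.
* The exclusive class label prioritizes movement over lick-aligned
  classes; neurons genuinely multiplexing movement and reward appear in
  the flags, not in the exclusive label.
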