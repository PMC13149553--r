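---
title: "Quantifying how neuronal firing encodes locomotion speed"
author: "speedenc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying how neuronal firing encodes locomotion speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedenc)
```

## The scientific question

In head-fixed rodents on a turntable, a subset of cortical and midbrain
neurons — "R-neurons" — increase their firing seconds before a spontaneous
running bout and track the animal's speed throughout it, while remaining
insensitive to sensory stimuli (sound, light, air puff). Two quantities
characterize this coupling:

* the **temporal relationship** — firing leads speed by a lag of order one
  to two seconds, estimated from the cross-correlation function (CCF) between
  the binned firing rate and the speed trace; and
* the **quantitative relationship** — once the two curves are aligned at the
  optimal lag, speed saturates in firing rate according to the single-phase
  association model

  $$v = v_m \left(1 - e^{-(f - f_0)/\tau}\right),$$

  where $f_0$ is the initial firing rate (spikes/s), $v_m$ the asymptotic
  maximum speed (cm/s), and $\tau$ the firing effect constant: the rise in
  firing above $f_0$ at which speed reaches $v_m(1 - e^{-1}) = 63.2\%$ of its
  maximum. A small $\tau$ means a small increment of firing buys a large
  fraction of the maximal speed — high behavioural gain.

The same saturating law describes optogenetic dose–response curves: driving
the relevant projection neurons at pulse frequencies $F$ of 1–40 Hz evokes
running (or, for the collicular pathway, backing away and post-stimulation
rebound running) whose peak speed follows
$v_m(1 - e^{-(F - f_0)/\tau_s})$ with a stimulation effect constant $\tau_s$.

`speedenc` implements the full analysis chain — event detection, trial
labelling, R-neuron classification, CCF lag estimation with a permutation
null, model fitting with population normalization, and dose–response
analysis — together with a synthetic-session generator that provides ground
truth for every stage.

## Pipeline stages and the parameters that matter

`analysis_config()` holds all fixed constants. The ones that shape results:

| parameter | default | units | role |
|---|---|---|---|
| `run_threshold` | 0.5 | cm/s | running onset = first sample with speed above this gate |
| `psth_bin` | 0.010 | s | PSTH/PETH bin width for stimulus/onset alignment |
| `heatmap_bin` | 0.1 | s | bin for population heatmaps and firing-window PETHs |
| `sdf_sigma` | 0.010 | s | Gaussian spike-density kernel SD |
| `ccf_bin`, `ccf_lag_max` | 0.1, 10 | s | CCF grid: 201 lags over [-10, 10] s |
| `ccf_smooth_bins` | 11 | bins | centered moving average on both binned series |
| `n_permutations` | 1000 | — | circular shifts for the CCF null |
| `sensory_running_window` | 3 | s | stimulus-to-run window for trial labelling |
| `baseline_period` | (-10, -5) | s | stationary baseline before running onset |
| `alpha` | 0.05 | — | level of the rank tests and the permutation rule |

Three of these deserve comment.

**`ccf_smooth_bins` (1.1 s moving average).** Binned spike counts at 0.1 s
are dominated by Poisson noise (a 10 spikes/s neuron yields counts of 0–2
per bin), which deflates the Pearson correlation far below what the
underlying rate process supports. Recording-analysis practice smooths both
the rate and speed curves before correlating; we use a symmetric moving
average, which cannot bias the lag estimate, and a width of 11 bins, at
which synthetic R-neurons at our default noise reproduce peak correlations
of about 0.85–0.9 — the range reported for real R-neurons. Narrower windows
lower $r_{max}$ without improving lag accuracy.

**`sensory_running_window` (3 s).** The window separating stimulus-evoked
from spontaneous runs is inherited from prior work in this paradigm and has
no published value; 3 s comfortably covers reported sensory-evoked running
latencies while leaving most of a session's quiet time usable. It is a
required, overridable setting rather than a buried constant.

**`baseline_period` ((-10, -5) s).** The stationary baseline must precede
the longest reported pre-running activity window (about -3 s); starting it
at -10 s with a 5-s span keeps it clear of pre-run activity while providing
enough bins for a stable SD estimate.

## Classification: two stages, one multiplicity decision

A neuron is an R-neuron iff it is running-related and not
sensory-responsive. Stage one compares, per modality, the mean rate in the
1-s post-stimulus window of no-run trials against the 1-s pre-stimulus
baseline (one-sided Wilcoxon signed-rank: the hypothesis is directional).
Stage two compares the rate in the neuron's own firing window (or the
configured default) against the stationary baseline across spontaneous runs.

Because the sensory call aggregates three modality tests by "significant for
at least one", leaving each at level $\alpha$ puts the family-wise error of
the aggregated call near $3\alpha$: about one in eight genuinely
running-related neurons would be discarded as "sensory" by chance, capping
attainable classification sensitivity near 0.86. `classify_neuron()`
therefore Holm-adjusts the three p-values before the neuron-level call
(per-modality raw p-values are still reported);
`modality_correction = "none"` restores the uncorrected variant.

The firing window itself is the first PETH bin whose rate exceeds
baseline mean + 2 SD, by default required to stay above threshold in every
bin until onset (`window_rule = "sustained"`); `"single"` accepts the first
crossing anywhere. The sustained rule is less sensitive to isolated noisy
bins and is the default because the window is meant to describe activity
that persists into movement onset. A degenerate baseline (SD = 0) falls
back to "any strict increase" and is flagged.

## CCF, optimal lag, and the permutation null

The reported CCF is the Pearson correlation of firing$(t)$ with
speed$(t + \mathrm{lag})$ over the truncated overlapping segment, positive
lags meaning firing leads. The peak plateau is the contiguous lag range
within `plateau_tol` ($10^{-3}$) of the maximum; the optimal lag is the
plateau midpoint, which is robust when the peak is flat-topped, as observed
in the recordings this analysis emulates. The FWHM takes the minimum
observed correlation on the grid as its floor (a half-maximum needs a floor
reference, and the curve has no natural zero), with crossings located by
linear interpolation.

Significance uses 1000 random circular shifts of the speed series, each at
least `ccf_lag_max` away from zero on both sides of the circle. One subtlety
is load-bearing: if the observed statistic is computed on truncated overlaps
while null statistics are computed on wrapped (shifted) series, the null
values mix two unrelated alignments per lag, their distribution is
light-tailed relative to the observed one, and the test rejects far too
often (we measured a type-I rate of about 0.15 at nominal 0.05). We
therefore compute the *test statistic* — observed and null alike — on the
circular correlation, where every lag pairs all $n$ samples. Rotations then
form a group, the observed alignment is exchangeable with the shifted ones
under independence, and the test calibrates (measured type-I about
0.05–0.06 on independent AR(1) pairs at 15-minute series length with 1000
shifts; the small residue reflects the guard excluding the shifts most
correlated with the observed window, and the p-value's add-one estimator
never returns 0). The reported correlation curve and its peak statistics
remain truncated-overlap.

## Model fitting

`fit_single_phase()` uses bounded Levenberg–Marquardt least squares:
$v_m \in (0, 10 \max v]$, $\tau > 0$, and $f_0 \ge -5$ spikes/s (a slightly
negative $f_0$ absorbs noise near the origin and is flagged). Starts are
$v_m^{(0)} = 1.05\max v$, $f_0^{(0)} = \min f$,
$\tau^{(0)} = (\max f - \min f)/2$, with five jittered restarts if the first
attempt fails or explains little variance. Noiseless forward-generated data
is recovered to better than $10^{-6}$ relative error. The regression F-test
compares each model against a constant; the linear comparison reports
$\Delta R^2$ and small-sample AIC side by side rather than a single
non-nested test, because the saturating and linear models are not nested
and a textbook extra-sum-of-squares F-test between them is not defined.

**Normalization.** To compare effect constants within a group, each
neuron's minimum firing and minimum speed are subtracted, speed is rescaled
by (group mean $v_m$)/(neuron $v_m$) using the *fitted* $v_m$ (the
population analysis explicitly fixes $v_m$ to its mean, which is a fitted
quantity), and $\tau$ is refit with $f_0 = 0$ and $v_m$ fixed at the group
mean. On synthetic groups sharing a true $\tau$, the refit values collapse
to it (CV < 0.1 at 2% speed noise) and a 2:1 between-group ratio is
preserved within a few percent.

**Dose–response fits** reuse the same core with frequency as abscissa and
the offset bounded to $[0, \min F]$ — the offset plays the role of a
threshold frequency, and letting it wander above the lowest tested
frequency would make the low-frequency points extrapolations.

## What the synthetic generator does and does not emulate

The generator produces: trapezoidal running bouts (1-s linear ramps, plateau
at the bout's peak speed) at least 12 s apart; signed speed with Gaussian
sensor noise (SD 0.1 cm/s — small enough that the 0.5 cm/s gate does not
fire on noise, as with a real rotary encoder's quantization floor);
R-neuron rate traces from the inverse model
$f(t) = f_0 - \tau \ln(1 - |v(t + \mathrm{lag})|/v_m)$ with speed clipped at
$0.99\,v_m$ (the inverse diverges at $v = v_m$); sensory neurons with a
rectangular rate bump during each stimulus plus a 200-ms exponential decay
(amplitude $3\sqrt{f_0}$, three baseline-Poisson SDs of the 1-s count);
unrelated neurons at constant rate; spikes by Poisson thinning; and
optogenetic trial tables on the 9-frequency, 10-trial design with
monotone-decreasing latency $0.3 + 2 e^{-F/10}$ s.

Population defaults emulate the reported statistics: lags of
$2.064 \pm 0.273$ s (TeA-like) and $0.903 \pm 0.228$ s (dPAG-like), a
TeA:dPAG effect-constant ratio near 2, $v_m$ tied to $\tau$ through the
reported linear relation $v_m \approx 1.43\tau + 7.37$, and noise levels at
which recovered peak correlations land in the reported 0.85–0.9 band.

Deliberately *not* emulated: bursting or refractory spike statistics,
rate adaptation within bouts, non-stationary baselines, behavioural
variability in bout shape, electrode drift, or any circuit dynamics
(the inhibitory interactions that produce stopping and rebound behaviours
are represented only through the labelled trial tables, not simulated).
Passing tests therefore demonstrate that the *analysis* recovers what the
*model class* generates — they do not validate the model against real
recordings, which this package has no access to.

## Numerical choices and degenerate inputs

* Bins are half-open `[edge, edge + width)`; a spike exactly at an event
  belongs to the first post-event bin.
* Running onsets sit on the first sample strictly above threshold — no
  interpolation, matching the sample-based onset definition.
* Sub-gap dips (< 0.5 s) within a run are bridged; events shorter than
  0.5 s are dropped (encoder jitter suppression).
* Constant heatmap rows min-max scale to 0; neurons with no qualifying
  events are omitted with a warning.
* Zero-variance segments at a CCF lag yield `NA` at that lag, not an error.
* The permutation p-value uses the add-one estimator, so the smallest
  attainable value with 1000 shifts is 1/1001; claims below $10^{-4}$
  cannot be produced with this estimator and shuffle count.
* All generators and the pipeline are deterministic given a seed; child
  seeds are derived with double-precision arithmetic folded into the 32-bit
  integer range.

## Problem sizes used by the test suite

The packaged checks run on 600-s synthetic sessions with 20 bouts
(100 seeds for lag recovery), 500 AR(1) pairs of 9000 bins with 1000 shifts
each for permutation calibration, a 100-neuron mixed population for
classifier performance, 10-neuron groups for normalization, and 200
replicates of the 9 x 10 optogenetic design. These sizes give Monte Carlo
standard errors comfortably inside each check's tolerance while keeping the
full suite under a minute of computation for most modules.

## Known limitations

* **Errors-in-variables bias.** Fitting $v$ on the *measured* (binned,
  smoothed) firing rate leaves Poisson noise in the abscissa; at desk noise
  levels this linearizes the scatter and inflates fitted $\tau$ and $v_m$
  from full-session pipelines by severalfold, even though the fitted curve
  tracks the data over the observed range and $R^2$ is high. Lag estimates,
  classification and the pairs-level analyses are unaffected.
  `evaluate_against_truth()` reports the inflation honestly.
* The optimal lag is quantized to the 0.1-s CCF grid.
* The permutation test retains a small (+0.005 to +0.01) type-I excess from
  the guarded shift range; the add-one p-values remain valid.
* `time_difference_stats()` fits a Gaussian to a *histogram* by least
  squares (as the population figures do); it is a descriptive fit, not a
  maximum-likelihood density estimate, and is sensitive to bin count at
  small n.

## A minimal walk-through

```{r example, eval = FALSE}
library(speedenc)

# A study-like synthetic session: 20 bouts, 24 sensory stimuli, 6 neurons.
sch <- random_bout_schedule(600, n_bouts = 20, seed = 1)
stim <- quiet_stimulus_schedule(sch, 600, seed = 2)
spec <- population_spec("TeA", n_neurons = 6,
                        fractions = c(R_neuron = 0.5, sensory = 0.25,
                                      unrelated = 0.25))
gen <- generate_population_session(spec, sch, stim, seed = 3)

rep <- run_pipeline(gen$session, analysis_config(rng_seed = 7))
evaluate_against_truth(rep, gen$truth)
```
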