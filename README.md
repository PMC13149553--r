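# speedenc

Quantitative analysis of how neuronal firing rate encodes locomotion speed.

In head-fixed rodents, "R-neurons" in temporal association cortex (TeA) and
dorsal periaqueductal grey (dPAG) ramp up their firing seconds before a
spontaneous running bout and track running speed throughout it, while
ignoring sensory stimuli. `speedenc` is an R package for the analysis chain
that establishes and quantifies this coupling from spike-time and
speed-trace recordings:

* **Event detection & trial labelling** — running onsets at a 0.5 cm/s gate,
  spontaneous vs stimulus-evoked runs, no-run stimulus trials.
* **R-neuron classification** — paired Wilcoxon tests: no post-stimulus rate
  increase for any modality (sound / light / air puff), and elevated firing
  in the pre-running window relative to a stationary baseline.
* **Cross-correlation lag estimation** — Pearson correlation of binned
  firing rate against speed over lags of [-10, 10] s in 0.1-s steps, peak
  plateau statistics (r_max, optimal lag, FWHM), and a circular-shift
  permutation null (1000 shifts).
* **Encoding-model fitting** — after aligning firing to speed at the optimal
  lag, bounded nonlinear least squares of the single-phase association model

  v = v_m (1 − e^−(f − f0)/τ)

  where `f0` is the initial firing rate, `v_m` the maximum speed, and `τ`
  the firing effect constant (the rise in firing at which speed reaches
  63.2% of `v_m`), plus linear comparison, peak-to-peak population fits,
  and population normalization that refits a shared `τ` with `f0 = 0` and
  `v_m` fixed at the group mean.
* **Optogenetic dose–response analysis** — per-trial peak speed, behaviour
  (running / backing away / stopping / rebound), block-averaged
  speed-vs-frequency curves fit with the same saturating model (`τ_s`,
  `v_m`), linear frequency→firing-rate conversion slopes, and latency
  curves.
* **Synthetic sessions with ground truth** — inhomogeneous-Poisson spike
  trains whose rate follows the inverse encoding model with a
  firing-leads-speed lag, mixed populations (R / sensory / unrelated), and
  opto trial tables, so every stage of the pipeline can be validated.

## Worked example

```r
library(speedenc)

# A study-like synthetic session: 600 s, 20 running bouts, 24 sensory
# stimuli, 6 neurons (3 R-neurons, 2 sensory, 1 unrelated by fractions).
sch  <- random_bout_schedule(600, n_bouts = 20, seed = 1)
stim <- quiet_stimulus_schedule(sch, 600, seed = 2)
spec <- population_spec("TeA", n_neurons = 6,
                        fractions = c(R_neuron = 0.5, sensory = 0.25,
                                      unrelated = 0.25))
gen  <- generate_population_session(spec, sch, stim, seed = 3)

rep <- run_pipeline(gen$session, analysis_config(rng_seed = 7))
rep$TeA_001$label
#> <neuron_label> TeA_001: sensory=FALSE running=TRUE R-neuron=TRUE
rep$TeA_001$ccf[c("r_max", "lag_star", "p_perm")]
#> r_max = 0.853 at lag* = 2.00 s (p_perm = 0.005994)

evaluate_against_truth(rep, gen$truth)
#> <evaluation_report> R-neuron detection: TP=2 FP=0 FN=0 TN=4
#>   sensitivity = 1.000, specificity = 1.000
#>   tau medARE = 8.457, v_m medARE = 4.176, lag MAD = 0.036 s
```

Reading the output: both ground-truth R-neurons in this session are
detected with no false positives; the injected 2.04-s encoding lag is
recovered to 0.04 s by the CCF; and the peak correlation (0.853) sits in
the 0.85–0.9 band typical of real R-neurons. The large `tau` median
absolute relative error is expected at full-pipeline noise: Poisson noise
in the firing-rate abscissa linearizes the saturating scatter and inflates
the fitted `(tau, v_m)` jointly, even though the fitted curve tracks the
data (see the methods vignette, "Known limitations"). Pairs-level fits
without abscissa noise recover parameters to high precision.

Dose–response analysis works the same way from an optogenetic trial table:

```r
par <- stim_response_params(tau_s = 14.32, v_m = 22.81, trial_noise_sd = 2)
tab <- generate_optostim_trials(par, seed = 1)      # 9 frequencies x 10 trials
pts <- block_average(tab, 10)
fit_stimulation_curve(pts$frequency, pts$mean_speed)
#> <stim_fit> v_m = 23.01 cm/s, tau_s = 14.21 Hz, f0 = 0.00 Hz (R2 = 0.996)
```

## Package layout

| path | contents |
|---|---|
| `R/session-io.R` | data model (`spike_train`, `speed_trace`, `session`, `analysis_config`), TSV/JSON readers and writers, `run_pipeline()` |
| `R/synthetic-data.R` | bout schedules, inverse-model rate traces, Poisson thinning, population and opto-trial generators |
| `R/preprocessing.R` | running-event detection, trial labelling, PETHs, spike density, firing windows, heatmaps |
| `R/classification.R` | paired rank tests and the two-stage R-neuron criterion |
| `R/ccf.R` | binning, truncated-overlap CCF, peak statistics, circular-shift permutation test |
| `R/encoding-model.R` | single-phase association fits, linear comparison, peak-to-peak, normalization, parameter relations |
| `R/stim-response.R` | behaviour extraction, block averaging, dose–response fits, latency curves |
| `R/reporting.R` | population summaries and evaluation against ground truth |

The methods vignette (`vignettes/speed-encoding.Rmd`) documents the model,
parameter defaults with units, the design decisions behind the permutation
statistic and the classification multiplicity correction, what the
synthetic generator does and does not emulate, and known limitations.
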