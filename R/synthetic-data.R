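# Synthetic sessions with the statistical structure the analysis assumes:
# bout-shaped speed traces, rate traces from the inverse single-phase
# association model with a firing-leads-speed lag, inhomogeneous-Poisson spike
# trains, mixed populations with ground-truth labels, and optogenetic trial
# tables.

#' Per-neuron encoding parameters
#'
#' Parameters of the speed-encoding model for one simulated neuron. The
#' forward model maps firing rate to speed as
#' `v = v_m (1 - exp(-(f - f0)/tau_f))`; the generator applies its inverse to
#' a speed trace to produce a rate trace, with firing leading speed by `lag`.
#'
#' @param f0 Baseline/initial firing rate, spikes/s (>= 0).
#' @param tau_f Firing effect constant, spikes/s (> 0).
#' @param v_m Maximum (asymptotic) speed, cm/s (> 0).
#' @param lag Seconds by which firing leads speed (>= 0).
#' @param rate_noise_sd Additive Gaussian rate noise, spikes/s.
#' @param speed_noise_sd Speed noise used when generating traces, cm/s.
#' @return An object of class `encoding_params`.
#' @export
encoding_params <- function(f0 = 3, tau_f = 20, v_m = 30, lag = 2,
                            rate_noise_sd = 0, speed_noise_sd = 0.1) {
  if (f0 < 0) stop_validation("f0 must be >= 0")
  if (tau_f <= 0) stop_validation("tau_f must be > 0")
  if (v_m <= 0) stop_validation("v_m must be > 0")
  if (lag < 0) stop_validation("lag must be >= 0")
  structure(list(f0 = f0, tau_f = tau_f, v_m = v_m, lag = lag,
                 rate_noise_sd = rate_noise_sd,
                 speed_noise_sd = speed_noise_sd),
            class = "encoding_params")
}

#' Population specification for the session generator
#'
#' Defaults emulate the recorded populations: TeA-like neurons lead speed by
#' 2.064 +/- 0.273 s, dPAG-like neurons by 0.903 +/- 0.228 s; the firing effect
#' constant for TeA is about twice that of dPAG, and `v_m` is tied to `tau_f`
#' through the population-level linear relation `v_m ~ 1.43 tau + 7.37`.
#'
#' @param group `"TeA"` or `"dPAG"`.
#' @param n_neurons Number of neurons.
#' @param fractions Named numeric vector with class fractions
#'   `c(R_neuron=, sensory=, unrelated=)` summing to 1.
#' @param f0_mean,f0_sd Baseline rate distribution, spikes/s.
#' @param tau_f_mean,tau_f_sd Firing effect constant distribution, spikes/s.
#' @param vm_sd Scatter of `v_m` around the linear relation to `tau_f`, cm/s.
#' @param lag_mean,lag_sd Firing-leads-speed lag distribution, s.
#' @param rate_noise_sd,speed_noise_sd Noise levels passed to
#'   [encoding_params()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(group = c("TeA", "dPAG"),
                            n_neurons = 30,
                            fractions = c(R_neuron = 1, sensory = 0, unrelated = 0),
                            f0_mean = 3, f0_sd = 1,
                            tau_f_mean = if (group[1] == "dPAG") 10 else 20,
                            tau_f_sd = if (group[1] == "dPAG") 2 else 4,
                            vm_sd = 2,
                            lag_mean = if (group[1] == "dPAG") 0.903 else 2.064,
                            lag_sd = if (group[1] == "dPAG") 0.228 else 0.273,
                            rate_noise_sd = 0,
                            speed_noise_sd = 0.1) {
  group <- match.arg(group)
  fractions <- fractions[c("R_neuron", "sensory", "unrelated")]
  if (any(is.na(fractions)) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_validation("class fractions must be non-negative and sum to 1")
  }
  if (f0_sd < 0 || tau_f_sd < 0 || vm_sd < 0 || lag_sd < 0) {
    stop_validation("parameter SDs must be >= 0")
  }
  structure(list(group = group, n_neurons = as.integer(n_neurons),
                 fractions = fractions, f0_mean = f0_mean, f0_sd = f0_sd,
                 tau_f_mean = tau_f_mean, tau_f_sd = tau_f_sd, vm_sd = vm_sd,
                 lag_mean = lag_mean, lag_sd = lag_sd,
                 rate_noise_sd = rate_noise_sd,
                 speed_noise_sd = speed_noise_sd),
            class = "population_spec")
}

#' Running-bout schedule
#'
#' @param onsets Bout onset times, seconds.
#' @param durations Bout durations, seconds.
#' @param peak_speeds Bout plateau speeds, cm/s (positive; must exceed the
#'   running gate).
#' @param min_gap Minimum inter-bout gap in seconds (default 2).
#' @return An object of class `bout_schedule`.
#' @export
bout_schedule <- function(onsets = numeric(), durations = numeric(),
                          peak_speeds = numeric(), min_gap = 2) {
  n <- length(onsets)
  if (length(durations) != n || length(peak_speeds) != n) {
    stop_validation("onsets, durations and peak_speeds must have equal length")
  }
  if (n > 1L) {
    o <- order(onsets)
    onsets <- onsets[o]; durations <- durations[o]; peak_speeds <- peak_speeds[o]
    gaps <- onsets[-1] - (onsets[-n] + durations[-n])
    if (any(gaps < min_gap)) {
      stop_validation("bouts overlap or violate the minimum inter-bout gap")
    }
  }
  if (any(peak_speeds <= 0)) stop_validation("peak speeds must be positive")
  structure(list(onsets = onsets, durations = durations,
                 peak_speeds = peak_speeds, min_gap = min_gap),
            class = "bout_schedule")
}

#' Draw a random, non-overlapping bout schedule
#'
#' Convenience builder for the study-like condition: spontaneous running bouts
#' scattered over the session with gaps long enough that the 10-s pre-onset
#' exclusion used by the heatmap analysis retains most events.
#'
#' @param session_duration Session length, seconds (default 600).
#' @param n_bouts Number of bouts (default 20).
#' @param duration_range,peak_range Bout duration (s) and plateau speed (cm/s)
#'   ranges sampled uniformly.
#' @param min_gap Minimum inter-bout gap, seconds (default 12).
#' @param seed RNG seed.
#' @return A [bout_schedule()].
#' @export
random_bout_schedule <- function(session_duration = 600, n_bouts = 20,
                                 duration_range = c(4, 8),
                                 peak_range = c(8, 18),
                                 min_gap = 12, seed = NULL) {
  with_seed(seed, {
    durations <- stats::runif(n_bouts, duration_range[1], duration_range[2])
    peaks <- stats::runif(n_bouts, peak_range[1], peak_range[2])
    # Place bouts by distributing the free time between them.
    slack <- session_duration - sum(durations) - min_gap * (n_bouts + 1)
    if (slack < 0) stop_validation("session too short for requested bouts")
    cuts <- sort(stats::runif(n_bouts, 0, slack))
    onsets <- min_gap + cuts + cumsum(c(0, durations[-n_bouts] + min_gap))
    bout_schedule(onsets, durations, peaks, min_gap = min_gap)
  })
}

#' Generate a bout-shaped speed trace
#'
#' Each bout is a trapezoid: linear 1-s ramps up and down with a plateau at
#' `peak_speed` (bouts shorter than 2 s become triangles). Gaussian noise of
#' SD `speed_noise_sd` is added everywhere; between bouts the trace is pure
#' noise around zero.
#'
#' @param schedule A [bout_schedule()].
#' @param session_duration Trace length, seconds.
#' @param sampling_rate Hz (default 100).
#' @param speed_noise_sd Noise SD, cm/s (default 0.2).
#' @param seed RNG seed.
#' @return A [speed_trace()].
#' @export
generate_bouts_and_speed <- function(schedule, session_duration,
                                     sampling_rate = 100,
                                     speed_noise_sd = 0.1, seed = NULL) {
  stopifnot(inherits(schedule, "bout_schedule"))
  n <- round(session_duration * sampling_rate)
  tt <- (seq_len(n) - 1L) / sampling_rate
  v <- numeric(n)
  ramp <- 1  # seconds
  for (i in seq_along(schedule$onsets)) {
    on <- schedule$onsets[i]; du <- schedule$durations[i]
    pk <- schedule$peak_speeds[i]
    r <- min(ramp, du / 2)
    x <- tt - on
    in_bout <- x >= 0 & x <= du
    shape <- pmin(1, pmin(x, du - x) / r)
    v[in_bout] <- v[in_bout] + pk * shape[in_bout]
  }
  with_seed(seed, {
    if (speed_noise_sd > 0) v <- v + stats::rnorm(n, 0, speed_noise_sd)
    speed_trace(v, sampling_rate = sampling_rate)
  })
}

#' Firing-rate trace implied by a speed trace (inverse encoding model)
#'
#' Inverts the single-phase association model: with firing leading speed by
#' `lag`, the rate at time `t` is
#' `f(t) = f0 - tau_f * log(1 - |v(t + lag)| / v_m)`.
#' Speed magnitudes are clipped at `0.99 * v_m` before the log so the rate is
#' finite everywhere; beyond the end of the trace the last sample is held.
#'
#' @param speed A [speed_trace()].
#' @param params An [encoding_params()].
#' @param seed RNG seed for the additive rate noise (only used when
#'   `params$rate_noise_sd > 0`).
#' @return Numeric vector of rates (spikes/s) on the speed sampling grid.
#' @export
rate_from_speed <- function(speed, params, seed = NULL) {
  stopifnot(inherits(speed, "speed_trace"), inherits(params, "encoding_params"))
  n <- length(speed$samples)
  shift <- round(params$lag * speed$sampling_rate)
  idx <- pmin(seq_len(n) + shift, n)
  v <- abs(speed$samples[idx])
  v <- pmin(v, 0.99 * params$v_m)
  rate <- params$f0 - params$tau_f * log(1 - v / params$v_m)
  if (params$rate_noise_sd > 0) {
    rate <- with_seed(seed, rate + stats::rnorm(n, 0, params$rate_noise_sd))
  }
  pmax(rate, 0)
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Candidate spikes are drawn from a homogeneous Poisson process at the
#' maximum rate and retained with probability `rate(t)/max_rate`. The expected
#' count equals the integral of the rate.
#'
#' @param rate Numeric rate vector, spikes/s, sampled at `sampling_rate`.
#' @param sampling_rate Hz of the rate grid.
#' @param neuron_id Identifier for the resulting train.
#' @param region Region label.
#' @param seed RNG seed.
#' @return A [spike_train()].
#' @export
sample_inhomogeneous_poisson <- function(rate, sampling_rate, neuron_id = "n1",
                                         region = "other", seed = NULL) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop_validation("rate must be finite and non-negative")
  }
  duration <- length(rate) / sampling_rate
  rmax <- max(rate)
  with_seed(seed, {
    if (rmax == 0) {
      return(spike_train(neuron_id, numeric(), duration, region))
    }
    n_cand <- stats::rpois(1L, rmax * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    idx <- pmin(floor(cand * sampling_rate) + 1L, length(rate))
    keep <- stats::runif(n_cand) < rate[idx] / rmax
    times <- cand[keep]
    times <- times[!duplicated(times)]  # guard strict ordering
    spike_train(neuron_id, times, duration, region)
  })
}

#' Generate a mixed population session with ground-truth labels
#'
#' R-neurons encode speed through [rate_from_speed()]; sensory-responsive
#' neurons fire at baseline plus an additive bump locked to stimulus onsets (a
#' rectangle during the stimulus followed by a 200-ms exponential decay) and
#' have no speed coupling; unrelated neurons fire at a constant rate. The bump
#' amplitude defaults to three times the Poisson SD of the 1-s baseline count,
#' i.e. `3 * sqrt(f0)` spikes/s.
#'
#' @param spec A [population_spec()].
#' @param schedule A [bout_schedule()].
#' @param stimuli A [stimulus_schedule()].
#' @param session_duration Seconds.
#' @param sampling_rate Hz (default 100).
#' @param bump_factor Sensory bump amplitude in units of `sqrt(f0)`
#'   (default 3).
#' @param seed RNG seed.
#' @return A list with elements `session` (a [session()]) and `truth` (a data
#'   frame: `neuron_id`, `class`, `f0`, `tau_f`, `v_m`, `lag`).
#' @export
generate_population_session <- function(spec, schedule, stimuli,
                                        session_duration = 600,
                                        sampling_rate = 100,
                                        bump_factor = 3, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_neurons
  counts <- round(spec$fractions * n)
  # Fix rounding drift on the largest class.
  counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
  classes <- rep(c("R_neuron", "sensory", "unrelated"), times = counts)

  with_seed(seed, {
    speed <- generate_bouts_and_speed(schedule, session_duration,
                                      sampling_rate = sampling_rate,
                                      speed_noise_sd = spec$speed_noise_sd,
                                      seed = NULL)
    max_peak <- if (length(schedule$peak_speeds)) max(schedule$peak_speeds) else 1
    tt <- speed_times(speed)
    trains <- vector("list", n)
    truth <- data.frame(neuron_id = sprintf("%s_%03d", spec$group, seq_len(n)),
                        class = classes,
                        f0 = NA_real_, tau_f = NA_real_, v_m = NA_real_,
                        lag = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      f0 <- max(0.5, stats::rnorm(1, spec$f0_mean, spec$f0_sd))
      cls <- classes[i]
      if (cls == "R_neuron") {
        tau_f <- max(2, stats::rnorm(1, spec$tau_f_mean, spec$tau_f_sd))
        v_m <- max(1.1 * max_peak,
                   1.43 * tau_f + 7.37 + stats::rnorm(1, 0, spec$vm_sd))
        lag <- max(0, stats::rnorm(1, spec$lag_mean, spec$lag_sd))
        par <- encoding_params(f0 = f0, tau_f = tau_f, v_m = v_m, lag = lag,
                               rate_noise_sd = spec$rate_noise_sd)
        rate <- rate_from_speed(speed, par, seed = NULL)
        truth[i, c("f0", "tau_f", "v_m", "lag")] <- c(f0, tau_f, v_m, lag)
      } else if (cls == "sensory") {
        rate <- rep(f0, length(tt))
        bump <- bump_factor * sqrt(f0)
        for (k in seq_len(nrow(stimuli))) {
          on <- stimuli$onset[k]; off <- on + stimuli$duration[k]
          during <- tt >= on & tt < off
          decay <- tt >= off & tt < off + 1
          rate[during] <- rate[during] + bump
          rate[decay] <- rate[decay] + bump * exp(-(tt[decay] - off) / 0.2)
        }
        truth$f0[i] <- f0
      } else {
        rate <- rep(f0, length(tt))
        truth$f0[i] <- f0
      }
      trains[[i]] <- sample_inhomogeneous_poisson(
        rate, sampling_rate, neuron_id = truth$neuron_id[i],
        region = if (spec$group %in% c("TeA", "dPAG")) spec$group else "other",
        seed = NULL)
    }
    list(session = session(trains, speed, stimuli,
                           metadata = list(group = spec$group)),
         truth = truth)
  })
}

#' Place sensory stimuli in the quiet periods of a bout schedule
#'
#' Distributes 1-s sound/light/air-puff stimuli into inter-bout gaps, keeping
#' each stimulus at least `clearance` seconds away from any bout so that
#' spontaneous runs stay spontaneous under the trial-labelling window.
#'
#' @param schedule A [bout_schedule()].
#' @param session_duration Seconds.
#' @param n_per_modality Stimuli per modality (default 8).
#' @param duration Stimulus duration, seconds (default 1).
#' @param clearance Minimum distance to any bout, seconds (default 5).
#' @param seed RNG seed.
#' @return A [stimulus_schedule()].
#' @export
quiet_stimulus_schedule <- function(schedule, session_duration,
                                    n_per_modality = 8, duration = 1,
                                    clearance = 5, seed = NULL) {
  with_seed(seed, {
    n_total <- 3L * n_per_modality
    # Candidate times on a coarse grid, kept clear of every bout.
    cand <- seq(clearance, session_duration - clearance - duration, by = 0.5)
    for (i in seq_along(schedule$onsets)) {
      on <- schedule$onsets[i]; off <- on + schedule$durations[i]
      cand <- cand[cand + duration < on - clearance | cand > off + clearance]
    }
    if (length(cand) < n_total) {
      stop_validation("not enough quiet time to place %d stimuli", n_total)
    }
    # Greedy spacing: sample then enforce >= 3 s separation between stimuli.
    picked <- numeric(0)
    for (t in sample(cand)) {
      if (all(abs(t - picked) >= duration + 3)) picked <- c(picked, t)
      if (length(picked) == n_total) break
    }
    picked <- sort(picked[seq_len(min(n_total, length(picked)))])
    modality <- rep(c("sound", "light", "air_puff"),
                    length.out = length(picked))
    stimulus_schedule(sample(modality), picked,
                      rep(duration, length(picked)))
  })
}

#' Stimulation-response parameters for optogenetic trials
#'
#' @param tau_s Stimulation effect constant, Hz (> 0).
#' @param v_m Maximum speed, cm/s (> 0).
#' @param f0_stim Frequency offset, Hz (>= 0).
#' @param trial_noise_sd Per-trial peak-speed noise, cm/s.
#' @param behaviour `"running"`, `"backing_away"` or `"rebound"`.
#' @return An object of class `stim_response_params`.
#' @export
stim_response_params <- function(tau_s = 14.32, v_m = 22.81, f0_stim = 0,
                                 trial_noise_sd = 2,
                                 behaviour = c("running", "backing_away",
                                               "rebound")) {
  behaviour <- match.arg(behaviour)
  if (tau_s <= 0) stop_validation("tau_s must be > 0")
  if (v_m <= 0) stop_validation("v_m must be > 0")
  structure(list(tau_s = tau_s, v_m = v_m, f0_stim = f0_stim,
                 trial_noise_sd = trial_noise_sd, behaviour = behaviour),
            class = "stim_response_params")
}

#' Generate an optogenetic trial table
#'
#' Peak speed per trial follows the forward single-phase association curve
#' `v_m (1 - exp(-(F - f0_stim)/tau_s))` plus Gaussian noise, floored at 0.
#' Backing-away trials carry negative-signed speeds. Latency per trial follows
#' the monotone-decreasing model `L_inf + A exp(-F/k)`
#' (defaults 0.3 + 2 exp(-F/10) s) plus small noise.
#'
#' @param params A [stim_response_params()].
#' @param frequencies Stimulation frequencies in Hz
#'   (default 1, 5, 10, ..., 40).
#' @param n_trials_per_freq Trials per frequency (default 10).
#' @param latency_pars Named vector `c(L_inf=, A=, k=)` of the latency model.
#' @param latency_noise_sd Latency noise SD, seconds (default 0.05).
#' @param seed RNG seed.
#' @return A data frame of class `opto_trial_table` with columns `frequency`,
#'   `trial_index`, `peak_speed` (signed), `behaviour`, `latency`.
#' @export
generate_optostim_trials <- function(params,
                                     frequencies = c(1, 5, 10, 15, 20, 25,
                                                     30, 35, 40),
                                     n_trials_per_freq = 10,
                                     latency_pars = c(L_inf = 0.3, A = 2, k = 10),
                                     latency_noise_sd = 0.05, seed = NULL) {
  stopifnot(inherits(params, "stim_response_params"))
  if (any(frequencies <= 0)) stop_validation("frequencies must be positive")
  if (n_trials_per_freq < 1) stop_validation("n_trials_per_freq must be >= 1")
  with_seed(seed, {
    freq <- rep(frequencies, each = n_trials_per_freq)
    n <- length(freq)
    mu <- params$v_m * (1 - exp(-(freq - params$f0_stim) / params$tau_s))
    mu <- pmax(mu, 0)
    speed <- mu + if (params$trial_noise_sd > 0) {
      stats::rnorm(n, 0, params$trial_noise_sd)
    } else 0
    speed <- pmax(speed, 0)
    lat <- latency_pars[["L_inf"]] +
      latency_pars[["A"]] * exp(-freq / latency_pars[["k"]])
    if (latency_noise_sd > 0) lat <- lat + stats::rnorm(n, 0, latency_noise_sd)
    lat <- pmax(lat, 0.01)
    sign <- if (params$behaviour == "backing_away") -1 else 1
    structure(
      data.frame(frequency = freq,
                 trial_index = rep(seq_len(n_trials_per_freq),
                                   times = length(frequencies)),
                 peak_speed = sign * speed,
                 behaviour = params$behaviour,
                 latency = lat, stringsAsFactors = FALSE),
      class = c("opto_trial_table", "data.frame")
    )
  })
}
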