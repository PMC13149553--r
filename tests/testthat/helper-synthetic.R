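# Shared fixtures, built in code.

# A flat trace with one rectangular speed step.
step_trace <- function(duration = 60, fs = 100, on = 10, len = 5, level = 20) {
  v <- numeric(duration * fs)
  idx <- seq(on * fs + 1, (on + len) * fs)
  v[idx] <- level
  speed_trace(v, sampling_rate = fs)
}

# Deterministic small session: one encoding neuron over a bout-shaped trace.
toy_session <- function(seed = 1, n_bouts = 12, duration = 400,
                        params = encoding_params()) {
  sch <- random_bout_schedule(duration, n_bouts = n_bouts, seed = seed)
  sp <- generate_bouts_and_speed(sch, duration, seed = seed + 1)
  rate <- rate_from_speed(sp, params)
  st <- sample_inhomogeneous_poisson(rate, sp$sampling_rate,
                                     neuron_id = "n1", seed = seed + 2)
  session(list(st), sp)
}

# Regular spike times (strictly increasing) on [0, duration).
regular_spikes <- function(rate, duration, id = "n1") {
  spike_train(id, seq(0, duration - 1e-9, by = 1 / rate), duration)
}
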