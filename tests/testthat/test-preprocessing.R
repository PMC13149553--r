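# Event detection, trial labelling, PETHs, spike density, firing windows,
# heatmaps.

test_that("running events are detected at threshold crossings", {
  fs <- 100
  # All-zero trace: no events.
  expect_equal(nrow(detect_running_events(speed_trace(numeric(1000), fs))), 0)

  # Step to 20 cm/s at t = 10 s for 5 s: one event, onset within one sample.
  tr <- step_trace(on = 10, len = 5, level = 20)
  ev <- detect_running_events(tr)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset - 10), 1 / fs + 1e-9)
  expect_equal(ev$peak_speed, 20)

  # Two bursts separated by 0.05 s merge under min_gap = 0.2 s.
  v <- numeric(1000)
  v[101:200] <- 10          # 1.0-1.99 s
  v[206:305] <- 10          # gap of 5 samples = 0.05 s
  ev2 <- detect_running_events(speed_trace(v, fs), min_gap = 0.2)
  expect_equal(nrow(ev2), 1)

  # Idempotence and invariance to sub-threshold noise on a flat trace.
  set.seed(8)
  noise <- speed_trace(runif(2000, -0.2, 0.2), fs)
  expect_equal(nrow(detect_running_events(noise, threshold = 0.5)), 0)

  # Brute-force onset oracle on a random trace.
  set.seed(9)
  v3 <- abs(rnorm(3000, 0, 3))
  tr3 <- speed_trace(v3, fs)
  ev3 <- detect_running_events(tr3, threshold = 2, min_gap = 0.3,
                               min_duration = 0)
  if (nrow(ev3)) {
    first_above <- which(v3 > 2)[1]
    expect_equal(ev3$onset[1], (first_above - 1) / fs)
  }
})

test_that("trials are labelled by the sensory-running window", {
  fs <- 100
  tr <- step_trace(on = 10, len = 5, level = 20, duration = 30)
  ev <- detect_running_events(tr)

  # No stimuli: every run is spontaneous.
  lab0 <- label_trials(ev, stimulus_schedule(), tr, 3)
  expect_true(all(lab0$events$provenance == "spontaneous"))

  # Stimulus at 9 s, run onset 10 s, window 3 s: stimulus-evoked.
  stim <- stimulus_schedule("sound", 9, 1)
  lab1 <- label_trials(ev, stim, tr, 3)
  expect_equal(lab1$events$provenance, "stimulus_evoked")

  # Stimulus over flat-zero speed: a no-run trial.
  quiet <- speed_trace(numeric(30 * fs), fs)
  lab2 <- label_trials(detect_running_events(quiet), stim, quiet, 3)
  expect_true(lab2$stimuli$no_run)
})

test_that("PETH counting matches hand counts and brute force", {
  dur <- 10
  st <- spike_train("a", c(1.005, 1.012, 1.095), dur)
  p <- compute_peth(st, 1, window = c(0, 0.1), bin_width = 0.01)
  expect_equal(as.numeric(p$counts), c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(p$mean_rate[c(1, 2, 10)], rep(100, 3))

  # No spikes: all-zero counts.
  p0 <- compute_peth(spike_train("b", numeric(), dur), c(1, 2),
                     window = c(-1, 1), bin_width = 0.1)
  expect_true(all(p0$counts == 0))

  # Doubling trials with identical spike patterns keeps the mean rate.
  st2 <- spike_train("c", c(1.05, 2.05), dur)
  p1 <- compute_peth(st2, 1, window = c(0, 0.1), bin_width = 0.1)
  p2 <- compute_peth(st2, c(1, 2), window = c(0, 0.1), bin_width = 0.1)
  expect_equal(p1$mean_rate, p2$mean_rate)

  expect_error(compute_peth(st, numeric(), c(0, 1), 0.1), "no alignment")

  # Brute-force oracle on random instances.
  set.seed(10)
  for (i in 1:5) {
    times <- sort(runif(80, 0, 60))
    times <- times[!duplicated(times)]
    stt <- spike_train("r", times, 60)
    evs <- runif(4, 10, 50)
    bw <- 0.25
    p <- compute_peth(stt, evs, window = c(-2, 2), bin_width = bw)
    brute <- matrix(0, length(evs), 16)
    for (a in seq_along(evs)) {
      for (j in 1:16) {
        lo <- -2 + (j - 1) * bw
        brute[a, j] <- sum(times - evs[a] >= lo & times - evs[a] < lo + bw)
      }
    }
    expect_equal(unname(p$counts), brute)
  }
})

test_that("spike density integrates to the spike count", {
  dur <- 2
  # Empty train: zero density.
  sd0 <- spike_density(spike_train("a", numeric(), dur), sigma = 0.01,
                       grid = seq(0, dur, by = 0.001))
  expect_true(all(sd0$density == 0))

  # One spike: Gaussian peak 1/(sigma sqrt(2 pi)).
  sd1 <- spike_density(spike_train("b", 1, dur), sigma = 0.01,
                       grid = seq(0, dur, by = 0.001))
  expect_equal(max(sd1$density), stats::dnorm(0, sd = 0.01), tolerance = 1e-6)
  expect_equal(sum(sd1$density) * 0.001, 1, tolerance = 1e-4)

  # Integral conserves the count for a multi-spike train (away from edges).
  st <- spike_train("c", c(0.5, 0.9, 1.2, 1.21), dur)
  sdm <- spike_density(st, sigma = 0.01, grid = seq(0, dur, by = 0.001))
  expect_equal(sum(sdm$density) * 0.001, 4, tolerance = 1e-3)
})

test_that("firing windows follow the baseline + 2 SD rule", {
  # Hand-built PETH: baseline mean 2, SD 0.5; rates >= 3.1 from -1.8 s on.
  mk_peth <- function(rates, edges, bw) {
    structure(list(bin_edges = edges, counts = matrix(0, 1, length(rates)),
                   n_trials = 1, bin_width = bw, mean_rate = rates),
              class = "peth")
  }
  edges <- seq(-10, 0, by = 0.2)
  left <- edges[-length(edges)]
  base <- rep(c(1.5, 2.5), length.out = sum(left < -5))  # mean 2, SD ~0.5
  rates <- c(base, ifelse(left[left >= -5] >= -1.8, 3.5, 2.0))
  p <- mk_peth(rates, edges, 0.2)
  w <- detect_firing_window(p, baseline_period = c(-10, -5))
  expect_true(w$crossed)
  expect_equal(w$start, -1.8)
  expect_equal(w$end, 0)
  expect_equal(w$baseline_mean, mean(base))

  # Flat PETH equal to baseline: no window.
  pf <- mk_peth(rep(2, length(left)), edges, 0.2)
  pf$mean_rate <- c(base, rep(2, sum(left >= -5)))
  expect_false(detect_firing_window(pf, c(-10, -5))$crossed)

  # Crossing requires strictly exceeding baseline + 2 SD.
  thr <- w$baseline_mean + 2 * w$baseline_sd
  pe <- mk_peth(c(base, rep(thr, sum(left >= -5))), edges, 0.2)
  expect_false(detect_firing_window(pe, c(-10, -5))$crossed)
  pa <- mk_peth(c(base, rep(thr + 1e-9, sum(left >= -5))), edges, 0.2)
  expect_true(detect_firing_window(pa, c(-10, -5))$crossed)

  # Sustained rule: an early crossing with a later dip starts at the final
  # contiguous run; the single-bin rule starts at the first crossing.
  rr <- c(base, rep(2, sum(left >= -5)))
  idx5 <- which(left >= -5)
  rr[idx5[left[idx5] >= -4 & left[idx5] < -3.8]] <- 5   # isolated early burst
  rr[idx5[left[idx5] >= -1]] <- 5                       # sustained to onset
  pr <- mk_peth(rr, edges, 0.2)
  expect_equal(detect_firing_window(pr, c(-10, -5), rule = "sustained")$start, -1)
  expect_equal(detect_firing_window(pr, c(-10, -5), rule = "single")$start, -4)
})

test_that("time differences are summarised with a Gaussian histogram fit", {
  # Constant input: mean only, no fit.
  s0 <- time_difference_stats(rep(2, 10))
  expect_equal(s0$mean, 2)
  expect_equal(s0$sd, 0)
  expect_null(s0$fit)

  # Samples from the reported distribution recover its mean.
  set.seed(11)
  x <- rnorm(500, 2.225, 0.582)
  s1 <- time_difference_stats(x)
  expect_false(is.null(s1$fit))
  expect_lt(abs(s1$fit$mu - 2.225), 0.1)

  # A matched-size uniform sample fits a Gaussian worse than the normal one.
  u <- runif(500, 2.225 - 2, 2.225 + 2)
  s2 <- time_difference_stats(u)
  expect_gt(s1$fit$r_squared, s2$fit$r_squared)
})

test_that("heatmap rows are min-max scaled and events filtered", {
  sess <- toy_session(seed = 13, n_bouts = 10, duration = 400)
  hm <- build_heatmap(sess)
  expect_gte(nrow(hm), 1)
  expect_true(all(hm >= 0 & hm <= 1))
  expect_equal(unname(apply(hm, 1, min)), rep(0, nrow(hm)))
  expect_equal(unname(apply(hm, 1, max)), rep(1, nrow(hm)))

  # Two runs 4 s apart: the second is excluded by the 10-s criterion.
  fs <- 100
  v <- numeric(60 * fs)
  v[(20 * fs):(21 * fs)] <- 10
  v[(24 * fs):(25 * fs)] <- 10
  ev <- detect_running_events(speed_trace(v, fs))
  qual <- speedenc:::.qualifying_events(ev, 10, 0.5)
  expect_equal(nrow(ev), 2)
  expect_equal(nrow(qual), 1)
  expect_equal(qual$onset, ev$onset[1])

  # Row scaling is invariant to affine transforms of a neuron's rate: scaling
  # spike counts is impossible post hoc, so check on the rate vector directly.
  r <- c(1, 3, 2, 5, 4)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(mm(r), mm(2.5 * r + 7))
})
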