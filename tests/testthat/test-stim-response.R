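# Optogenetic trials: behaviour extraction, block averaging, dose-response
# fitting, frequency-to-rate conversion, latency curves.

test_that("peak speed extraction classifies constructed traces", {
  fs <- 100
  mk <- function(v) speed_trace(v, fs)
  zero <- numeric(40 * fs)

  # Flat trace: stopping, no latency.
  r0 <- extract_peak_speed(mk(zero), onset = 10, duration = 5)
  expect_equal(r0$behaviour, "stopping")
  expect_true(is.na(r0$latency))

  # Negative-going bump during stimulation: backing away.
  v1 <- zero
  v1[(12 * fs):(14 * fs)] <- -8
  r1 <- extract_peak_speed(mk(v1), onset = 10, duration = 5)
  expect_equal(r1$behaviour, "backing_away")
  expect_equal(abs(r1$peak_speed), 8)
  expect_equal(r1$latency, 2, tolerance = 0.02)

  # Bump only after offset: stopping during, rebound detected post-offset.
  v2 <- zero
  v2[(17 * fs):(19 * fs)] <- 12
  r2 <- extract_peak_speed(mk(v2), onset = 10, duration = 5)
  expect_equal(r2$behaviour, "stopping")
  expect_equal(r2$rebound_peak, 12)
  expect_equal(r2$rebound_latency, 2, tolerance = 0.02)

  expect_error(extract_peak_speed(mk(zero), onset = 38, duration = 5),
               "past")

  # Randomized toy traces: constructed label always recovered.
  set.seed(70)
  for (i in 1:25) {
    v <- numeric(40 * fs)
    kind <- sample(c("running", "backing_away", "stopping"), 1)
    if (kind != "stopping") {
      amp <- runif(1, 2, 20) * if (kind == "backing_away") -1 else 1
      a <- sample(seq(10 * fs, 13 * fs), 1)
      v[a:(a + fs)] <- amp
    }
    r <- extract_peak_speed(speed_trace(v, fs), onset = 10, duration = 5)
    expect_equal(r$behaviour, kind)
  }
})

test_that("block averaging preserves grand means", {
  par <- stim_response_params(trial_noise_sd = 2)
  tab <- generate_optostim_trials(par, seed = 4)
  b10 <- block_average(tab, 10)
  expect_equal(nrow(b10), 9)  # one point per frequency
  b1 <- block_average(tab, 1)
  expect_equal(nrow(b1), nrow(tab))
  expect_equal(sort(b1$mean_speed), sort(abs(tab$peak_speed)))
  # Mean of blocks equals the grand mean per frequency (equal block sizes).
  b5 <- block_average(tab, 5)
  for (fq in unique(tab$frequency)) {
    expect_equal(mean(b5$mean_speed[b5$frequency == fq]),
                 mean(abs(tab$peak_speed[tab$frequency == fq])))
  }
  expect_error(block_average(tab[0, ], 10), "empty")
})

test_that("dose-response curves are recovered", {
  # Noiseless: exact recovery of the generating constants.
  par <- stim_response_params(tau_s = 14.32, v_m = 22.81, f0_stim = 0,
                              trial_noise_sd = 0)
  tab <- generate_optostim_trials(par, seed = 1)
  pts <- block_average(tab, 10)
  fit <- fit_stimulation_curve(pts$frequency, pts$mean_speed)
  expect_equal(fit$tau_s, 14.32, tolerance = 1e-5)
  expect_equal(fit$v_m, 22.81, tolerance = 1e-5)

  # Backing-away magnitudes from the reported constant are recovered too.
  parb <- stim_response_params(tau_s = 13.87, v_m = 20, trial_noise_sd = 2,
                               behaviour = "backing_away")
  errs <- vapply(1:30, function(s) {
    tb <- generate_optostim_trials(parb, seed = s)
    pb <- block_average(tb, 10)
    ft <- fit_stimulation_curve(pb$frequency, pb$mean_speed)
    abs(ft$tau_s - 13.87) / 13.87
  }, numeric(1))
  expect_lt(median(errs), 0.2)

  # Fit on 10-trial block means equals the fit on per-frequency trial means.
  tabn <- generate_optostim_trials(stim_response_params(trial_noise_sd = 2),
                                   seed = 8)
  m1 <- block_average(tabn, 10)
  m2 <- aggregate(abs(peak_speed) ~ frequency, tabn, mean)
  f1 <- fit_stimulation_curve(m1$frequency, m1$mean_speed)
  f2 <- fit_stimulation_curve(m2$frequency, m2$`abs(peak_speed)`)
  expect_equal(f1$tau_s, f2$tau_s, tolerance = 1e-9)

  # Fitted curve is monotone non-decreasing over the fitted range.
  grid <- seq(1, 40, by = 0.5)
  pred <- single_phase(grid, f1$f0_stim, f1$v_m, f1$tau_s)
  expect_true(all(diff(pred) >= -1e-12))
})

test_that("frequency-to-rate slopes give the cross-synaptic ratio", {
  freq <- c(1, 5, 10, 15, 20, 25, 30, 35, 40)
  rates <- rbind(
    data.frame(class = "direct", frequency = freq, rate = 1.0 * freq + 2),
    data.frame(class = "trans", frequency = freq, rate = freq / 6 + 1))
  conv <- freq_to_rate_conversion(rates, "direct", "trans")
  expect_equal(conv$ratio, 6, tolerance = 1e-9)

  # Identical classes: ratio 1.
  rates2 <- rbind(
    data.frame(class = "a", frequency = freq, rate = 0.8 * freq),
    data.frame(class = "b", frequency = freq, rate = 0.8 * freq))
  expect_equal(freq_to_rate_conversion(rates2, "a", "b")$ratio, 1)

  # Slope invariant to frequency ordering.
  o <- sample(length(freq))
  rates3 <- data.frame(class = "a", frequency = freq[o],
                       rate = (0.8 * freq + 1)[o])
  expect_equal(freq_to_rate_conversion(rates3)$slopes[["a"]], 0.8,
               tolerance = 1e-12)

  expect_error(
    freq_to_rate_conversion(data.frame(class = "a", frequency = c(1, 5),
                                       rate = c(1, 2))),
    "3 frequencies")
})

test_that("latency decreases with frequency and converts to speed", {
  par <- stim_response_params(tau_s = 14.32, v_m = 22.81, trial_noise_sd = 2)
  tab <- generate_optostim_trials(par, seed = 12)
  pts <- block_average(tab, 10)
  fit <- fit_stimulation_curve(pts$frequency, pts$mean_speed)
  lc <- latency_curves(tab, fit)
  expect_lt(lc$spearman_rho, 0)
  expect_equal(lc$curve$converted_speed,
               fit$v_m * (1 - exp(-(lc$curve$frequency - fit$f0_stim) / fit$tau_s)),
               tolerance = 1e-12)

  # Constant latency: a zero-slope curve.
  tab2 <- tab
  tab2$latency <- 0.5
  lc2 <- latency_curves(tab2, fit)
  expect_true(all(lc2$curve$mean_latency == 0.5))
})
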