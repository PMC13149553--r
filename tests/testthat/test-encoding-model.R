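# Single-phase association fitting, lag alignment, model comparison,
# normalization, parameter relations.

test_that("the model reaches 63.2% of v_m at f = f0 + tau", {
  expect_equal(single_phase(2 + 20, 2, 30, 20) / 30, 1 - exp(-1),
               tolerance = 1e-12)
})

test_that("align_by_lag pairs firing with lag-shifted speed", {
  f <- 1:10; s <- 101:110
  # Zero lag: plain zip.
  p0 <- align_by_lag(f, s, 0, bin = 0.1)
  expect_equal(p0$f, f)
  expect_equal(p0$v, s)
  # Positive lag of 3 bins.
  p3 <- align_by_lag(f, s, 0.3, bin = 0.1)
  expect_equal(p3$f, 1:7)
  expect_equal(p3$v, 104:110)
  # Alignment undoes a constructed shift: correlation at lag 0 rises and the
  # re-estimated optimal lag collapses to ~0.
  set.seed(60)
  n <- 700; k <- 20
  x <- as.numeric(arima.sim(list(ar = 0.9), n + k))
  s2 <- x[1:n] + rnorm(n, 0, 0.01)
  f2 <- x[(k + 1):(n + k)]
  r0_before <- cor(f2, s2)
  cc <- cross_correlation(f2, s2)
  pr <- align_by_lag(f2, s2, cc$lag_star)
  expect_gt(cor(pr$f, pr$v), r0_before)
  cc2 <- cross_correlation(pr$f, pr$v)
  expect_lte(abs(cc2$lag_star), 0.1 + 1e-9)
})

test_that("noiseless pairs are recovered to high precision", {
  f <- seq(2, 60, length.out = 50)
  v <- single_phase(f, 2, 30, 20)
  fit <- fit_single_phase(f, v)
  expect_true(fit$converged)
  expect_equal(fit$f0, 2, tolerance = 1e-6)
  expect_equal(fit$v_m, 30, tolerance = 1e-6)
  expect_equal(fit$tau, 20, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # Fit is invariant to shuffling pair order.
  set.seed(61)
  o <- sample(length(f))
  fit2 <- fit_single_phase(f[o], v[o])
  expect_equal(fit2$tau, fit$tau, tolerance = 1e-9)

  expect_error(fit_single_phase(rep(3, 10), rep(5, 10)), "distinct")
})

test_that("tau is recovered within 10% under moderate speed noise", {
  set.seed(62)
  errs <- vapply(1:60, function(i) {
    f <- runif(100, 0, 60)
    v <- pmax(single_phase(f, 2, 30, 20) + rnorm(100, 0, 0.05 * 30), 0)
    ft <- fit_single_phase(f, v)
    abs(ft$tau - 20) / 20
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("model comparison prefers the generating model", {
  set.seed(63)
  f <- seq(0, 60, length.out = 80)
  # Linear ground truth: linear preferred, delta R2 <= tolerance.
  v_lin <- 2 + 0.4 * f + rnorm(80, 0, 0.5)
  fit_l <- fit_single_phase(f, v_lin)
  cmp_l <- fit_linear_and_compare(f, v_lin, fit_l)
  expect_lte(cmp_l$delta_r_squared, 0.02)

  # Saturating ground truth spanning > 2 tau: nonlinear wins clearly.
  v_sat <- single_phase(f, 2, 30, 15) + rnorm(80, 0, 0.5)
  fit_s <- fit_single_phase(f, v_sat)
  cmp_s <- fit_linear_and_compare(f, v_sat, fit_s)
  expect_gt(cmp_s$delta_r_squared, 0)
  expect_equal(cmp_s$preferred, "single_phase")

  # The comparison verdict is invariant to affine rescaling of v.
  v2 <- 2.5 * v_sat + 4
  fit_s2 <- fit_single_phase(f, v2 - min(v2))
  cmp_s2 <- fit_linear_and_compare(f, v2 - min(v2), fit_s2)
  expect_equal(cmp_s2$preferred, cmp_s$preferred)
  expect_equal(cmp_s2$delta_r_squared, cmp_s$delta_r_squared, tolerance = 0.05)
})

test_that("peak-to-peak fits recover a shared population curve", {
  set.seed(64)
  peak_f <- runif(30, 5, 70)
  peak_v <- single_phase(peak_f, 3, 28, 18) + rnorm(30, 0, 1)
  ptp <- peak_to_peak_fit(peak_f, pmax(peak_v, 0))
  expect_true(ptp$fit$converged)
  expect_lt(abs(ptp$fit$tau - 18) / 18, 0.4)
  expect_lt(abs(ptp$fit$v_m - 28) / 28, 0.2)

  # Degenerate input: identical peaks cannot be fitted.
  expect_error(peak_to_peak_fit(rep(10, 8), rep(20, 8)), "distinct")

  # Adding a neuron exactly on the fitted curve leaves parameters unchanged.
  f_new <- 40
  v_new <- predict(ptp$fit, f_new)
  ptp2 <- peak_to_peak_fit(c(peak_f, f_new), c(pmax(peak_v, 0), v_new))
  expect_equal(ptp2$fit$tau, ptp$fit$tau, tolerance = 1e-6)
  expect_equal(ptp2$fit$v_m, ptp$fit$v_m, tolerance = 1e-6)
})

test_that("normalization collapses a shared effect constant", {
  set.seed(65)
  make_group <- function(tau, n_neurons) {
    fits <- list(); pairs <- list()
    for (i in seq_len(n_neurons)) {
      f0 <- runif(1, 0, 6); vm <- runif(1, 15, 45)
      f <- seq(f0, f0 + 3 * tau, length.out = 120)
      v <- pmax(single_phase(f, f0, vm, tau) + rnorm(120, 0, 0.02 * vm), 0)
      fits[[i]] <- fit_single_phase(f, v)
      pairs[[i]] <- data.frame(f = f, v = v)
    }
    list(norm = normalize_population(fits, pairs,
                                     group = sprintf("tau%g", tau)),
         raw_tau = vapply(fits, `[[`, numeric(1), "tau"))
  }
  grp <- make_group(10, 8)
  g10 <- grp$norm
  expect_lt(g10$tau_sd / g10$tau_mean, 0.1)

  # Two groups with a 2:1 effect-constant ratio preserve it.
  g20 <- make_group(20, 8)$norm
  expect_lt(abs(g20$tau_mean / g10$tau_mean - 2) / 2, 0.15)

  # Normalization reduces tau dispersion relative to the same group's raw
  # three-parameter fits.
  expect_lt(g10$tau_sd, sd(grp$raw_tau) + 1e-9)

  # Single-neuron group: trivial normalization, tau matches its own fit.
  f <- seq(2, 40, length.out = 80)
  v <- single_phase(f, 2, 25, 12)
  ft <- fit_single_phase(f, v)
  ng <- normalize_population(list(ft), list(data.frame(f = f, v = v)))
  expect_equal(ng$per_neuron$tau_refit, 12, tolerance = 0.05)
})

test_that("parameter relations recover a generating line", {
  set.seed(66)
  tau <- runif(25, 5, 40)
  vm <- 1.43 * tau + 7.37 + rnorm(25, 0, 2)
  f0 <- runif(25, 0, 8)
  fits <- lapply(1:25, function(i) {
    structure(list(model = "single_phase", f0 = f0[i], v_m = vm[i],
                   tau = tau[i], converged = TRUE), class = "encoding_fit")
  })
  rel <- parameter_relations(fits)
  se_slope <- 2 / (sd(tau) * sqrt(25))
  expect_lt(abs(rel$vm_on_tau$slope - 1.43), 3 * se_slope)
  expect_lt(rel$vm_on_tau$p, 1e-6)

  # Exact collinear input: R^2 = 1.
  fits2 <- lapply(1:6, function(i) {
    structure(list(f0 = 1, v_m = 2 * i + 1, tau = i, converged = TRUE),
              class = "encoding_fit")
  })
  expect_equal(suppressWarnings(parameter_relations(fits2)$vm_on_tau$r_squared),
               1)

  expect_error(parameter_relations(fits[1:3]), "at least 5")
})
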