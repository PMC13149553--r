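# Single-phase association model fitting: lag alignment, nonlinear least
# squares, linear comparison, peak-to-peak analysis, population normalization
# and parameter-relation summaries.

#' The single-phase association model
#'
#' `v = v_m (1 - exp(-(f - f0)/tau))`: a saturating exponential mapping firing
#' rate (or stimulation frequency) to speed. At `f = f0 + tau` the speed
#' reaches `v_m (1 - exp(-1))`, i.e. 63.2% of its asymptote.
#'
#' @param f Abscissa: firing rate (spikes/s) or stimulation frequency (Hz).
#' @param f0 Initial rate/frequency offset.
#' @param v_m Asymptotic maximum speed, cm/s.
#' @param tau Effect constant, same units as `f`.
#' @return Predicted speed, cm/s.
#' @export
single_phase <- function(f, f0, v_m, tau) {
  v_m * (1 - exp(-(f - f0) / tau))
}

#' Align firing and speed series at the optimal lag
#'
#' Shifts the speed series backwards by `lag_star` (firing leads speed), so
#' each firing sample is paired with the speed it best predicts:
#' `(firing(t), speed(t + lag_star))` over the overlap.
#'
#' @param firing,speed Equal-length series on the `bin` grid.
#' @param lag_star Optimal lag in seconds (positive = firing leads).
#' @param bin Bin width in seconds.
#' @return A data frame with columns `f` and `v`.
#' @export
align_by_lag <- function(firing, speed, lag_star, bin = 0.1) {
  n <- length(firing)
  stopifnot(length(speed) == n)
  k <- round(lag_star / bin)
  if (abs(k) >= n) stop_validation("lag exceeds series length")
  if (k >= 0) {
    data.frame(f = firing[seq_len(n - k)], v = speed[seq_len(n - k) + k])
  } else {
    data.frame(f = firing[seq_len(n + k) - k], v = speed[seq_len(n + k)])
  }
}

# Shared nonlinear least-squares core. Bounds on f0 differ between the
# firing-rate fit (f0 >= -5, absorbing noise) and the stimulation-frequency
# fit (f0 in [0, min frequency]).
.fit_single_phase <- function(f, v, f0_lower = -5, f0_upper = Inf,
                              n_starts = 5) {
  keep <- is.finite(f) & is.finite(v)
  f <- f[keep]; v <- v[keep]
  if (length(unique(f)) < 5L) {
    stop_validation("need at least 5 distinct abscissa values to fit")
  }
  vmax <- max(v)
  if (vmax <= 0) stop_validation("speeds must include positive values")
  start0 <- list(f0 = max(min(f), f0_lower), v_m = 1.05 * vmax,
                 tau = max((max(f) - min(f)) / 2, 1e-3))
  lower <- c(f0 = f0_lower, v_m = 1e-8, tau = 1e-8)
  upper <- c(f0 = min(f0_upper, max(f)), v_m = 10 * vmax, tau = Inf)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  dat <- data.frame(f = f, v = v)
  try_fit <- function(st) {
    st$f0 <- min(max(st$f0, lower[["f0"]]), upper[["f0"]])
    tryCatch(
      minpack.lm::nlsLM(v ~ v_m * (1 - exp(-(f - f0) / tau)), data = dat,
                        start = st, lower = lower, upper = upper,
                        control = ctrl),
      error = function(e) NULL)
  }
  best <- try_fit(start0)
  best_sse <- if (is.null(best)) Inf else sum(stats::resid(best)^2)
  sstot <- sum((v - mean(v))^2)
  # Multi-start with jittered initial values when the first fit fails or
  # explains the data poorly.
  if (is.null(best) || (sstot > 0 && best_sse / sstot > 1e-3)) {
    set <- list()
    for (i in seq_len(n_starts)) {
      jit <- list(
        f0 = start0$f0 + (i - (n_starts + 1) / 2) * 0.2 * max(stats::sd(f), 1),
        v_m = start0$v_m * (0.6 + 0.3 * i),
        tau = start0$tau * 2^(i - (n_starts + 1) / 2))
      m <- try_fit(jit)
      if (!is.null(m)) {
        sse <- sum(stats::resid(m)^2)
        if (sse < best_sse) { best <- m; best_sse <- sse }
      }
    }
  }
  n <- length(v)
  if (is.null(best)) {
    return(list(coef = c(f0 = NA_real_, v_m = NA_real_, tau = NA_real_),
                r_squared = NA_real_, fit_p = NA_real_, n_points = n,
                sse = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(best)
  r2 <- if (sstot > 0) 1 - best_sse / sstot else NA_real_
  # Regression F-test against the constant model (3 parameters).
  df1 <- 2L; df2 <- n - 3L
  fstat <- if (df2 > 0 && best_sse > 0) {
    ((sstot - best_sse) / df1) / (best_sse / df2)
  } else Inf
  p <- if (df2 > 0) stats::pf(fstat, df1, df2, lower.tail = FALSE) else NA_real_
  list(coef = cf, r_squared = r2, fit_p = p, n_points = n, sse = best_sse,
       converged = TRUE)
}

#' Fit the single-phase association model to (firing, speed) pairs
#'
#' Nonlinear least squares with bounds (`v_m` in `(0, 10 max v]`, `tau > 0`,
#' `f0 >= -5` to absorb noise; a negative fitted `f0` is flagged).
#' Initialization uses `v_m = 1.05 max(v)`, `f0 = min(f)`,
#' `tau = (max f - min f)/2`, with five jittered restarts when needed.
#'
#' @param f Firing rates, spikes/s (at least 5 distinct values).
#' @param v Aligned speeds, cm/s (non-negative).
#' @return An object of class `encoding_fit` with fields `model`
#'   (`"single_phase"`), `f0`, `v_m`, `tau`, `r_squared`, `fit_p` (regression
#'   F-test against the constant model), `n_points`, `converged`,
#'   `negative_f0`.
#' @export
fit_single_phase <- function(f, v) {
  res <- .fit_single_phase(f, v, f0_lower = -5, f0_upper = Inf)
  if (!res$converged) {
    warning("single-phase fit did not converge; parameters are NA",
            call. = FALSE)
  }
  structure(
    list(model = "single_phase",
         f0 = unname(res$coef["f0"]), v_m = unname(res$coef["v_m"]),
         tau = unname(res$coef["tau"]),
         r_squared = res$r_squared, fit_p = res$fit_p,
         n_points = res$n_points, sse = res$sse,
         converged = res$converged,
         negative_f0 = isTRUE(res$coef[["f0"]] < 0)),
    class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit:%s> f0 = %.3f, v_m = %.3f, tau = %.3f (R2 = %.3f, p = %.3g, n = %d)%s\n",
              x$model, x$f0, x$v_m, x$tau, x$r_squared, x$fit_p, x$n_points,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Predicted speeds from an encoding fit
#' @param object An `encoding_fit`.
#' @param f Abscissa values.
#' @param ... Unused.
#' @export
predict.encoding_fit <- function(object, f, ...) {
  single_phase(f, object$f0, object$v_m, object$tau)
}

#' Linear fit and model comparison against the single-phase fit
#'
#' Ordinary least squares of `v` on `f` with its R-squared and regression
#' F-test, reported side by side with the nonlinear fit: `delta_r_squared =
#' R2_nonlinear - R2_linear` and small-sample AIC (AICc, computed from the
#' residual sum of squares on the same scale for both models).
#'
#' @param f,v The same pairs used for the nonlinear fit.
#' @param nonlinear An [fit_single_phase()] result on those pairs.
#' @return A list with `linear` (slope, intercept, r_squared, fit_p), `aicc`
#'   (named vector for both models), `delta_r_squared`, and `preferred`.
#' @export
fit_linear_and_compare <- function(f, v, nonlinear) {
  stopifnot(inherits(nonlinear, "encoding_fit"))
  if (stats::sd(f) == 0) stop_validation("zero variance in f")
  lmfit <- stats::lm(v ~ f)
  sm <- summary(lmfit)
  rss_lin <- sum(stats::resid(lmfit)^2)
  n <- length(v)
  aicc <- function(rss, k) {
    # Gaussian log-likelihood up to a shared constant; k includes sigma.
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  p_lin <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  out <- list(
    linear = list(slope = unname(stats::coef(lmfit)[2]),
                  intercept = unname(stats::coef(lmfit)[1]),
                  r_squared = sm$r.squared, fit_p = p_lin),
    aicc = c(single_phase = aicc(nonlinear$sse, 4),
             linear = aicc(rss_lin, 3)),
    delta_r_squared = nonlinear$r_squared - sm$r.squared)
  out$preferred <- if (out$aicc["single_phase"] < out$aicc["linear"]) {
    "single_phase"
  } else "linear"
  out
}

#' Population-level single-phase fit of per-neuron peaks
#'
#' Fits one single-phase association curve across neurons using each neuron's
#' peak firing rate and peak running speed, probing the encoding rule at the
#' extremes of the physiological range; also reports the linear comparison.
#'
#' @param peak_f Per-neuron peak firing rates, spikes/s.
#' @param peak_v Per-neuron peak speeds, cm/s.
#' @return A list with `fit` (an `encoding_fit`) and `comparison`
#'   (see [fit_linear_and_compare()]).
#' @export
peak_to_peak_fit <- function(peak_f, peak_v) {
  fit <- fit_single_phase(peak_f, peak_v)
  list(fit = fit, comparison = fit_linear_and_compare(peak_f, peak_v, fit))
}

#' Normalize a group of neurons and refit a shared effect constant
#'
#' Standardizes the running-firing curves within a group: per neuron, the
#' minimum firing rate and minimum speed are subtracted, speed is rescaled by
#' `group mean v_m / neuron v_m` (measured `v_m` = fitted `v_m`), and `tau`
#' is refit with `f0` fixed at 0 and `v_m` fixed at the group mean. If all
#' neurons share a true effect constant, the refit values converge to it.
#'
#' @param fits List of converged [fit_single_phase()] results (one per
#'   neuron; at least 2).
#' @param pairs_list List of data frames with columns `f`, `v` (the raw
#'   aligned pairs per neuron, same order as `fits`).
#' @param group Group label.
#' @return An object of class `normalized_fit`: `group`, `group_mean_vm`,
#'   `per_neuron` (data frame: `v_m`, `y_scale`, `x_shift`, `tau_refit`),
#'   `tau_mean`, `tau_sd`.
#' @export
normalize_population <- function(fits, pairs_list, group = "group") {
  stopifnot(length(fits) == length(pairs_list))
  ok <- vapply(fits, function(fz) isTRUE(fz$converged) && fz$v_m > 0,
               logical(1))
  if (any(!ok)) {
    warning(sprintf("%d neuron(s) excluded from normalization (no converged fit or v_m <= 0)",
                    sum(!ok)), call. = FALSE)
  }
  fits <- fits[ok]; pairs_list <- pairs_list[ok]
  if (length(fits) < 1L) stop_validation("no usable fits in group")
  vms <- vapply(fits, `[[`, numeric(1), "v_m")
  mean_vm <- mean(vms)
  per <- lapply(seq_along(fits), function(i) {
    d <- pairs_list[[i]]
    x_shift <- min(d$f)
    y_scale <- mean_vm / vms[i]
    f2 <- d$f - x_shift
    v2 <- (d$v - min(d$v)) * y_scale
    tau_refit <- .refit_tau(f2, v2, v_m_fixed = mean_vm)
    data.frame(v_m = vms[i], y_scale = y_scale, x_shift = x_shift,
               tau_refit = tau_refit)
  })
  per <- do.call(rbind, per)
  structure(
    list(group = group, group_mean_vm = mean_vm, per_neuron = per,
         tau_mean = mean(per$tau_refit), tau_sd = stats::sd(per$tau_refit)),
    class = "normalized_fit")
}

# One-parameter refit: v = v_m_fixed * (1 - exp(-f / tau)).
.refit_tau <- function(f, v, v_m_fixed) {
  dat <- data.frame(f = f, v = v)
  start <- list(tau = max((max(f) - min(f)) / 2, 1e-3))
  m <- tryCatch(
    minpack.lm::nlsLM(v ~ v_m_fixed * (1 - exp(-f / tau)), data = dat,
                      start = start, lower = c(tau = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(m)) NA_real_ else unname(stats::coef(m)["tau"])
}

#' Relations among fitted encoding parameters across neurons
#'
#' Ordinary least squares of `v_m` on `tau` (slope, intercept, F-test p) and
#' Pearson correlations of `f0` with `tau` and with `v_m`.
#'
#' @param fits List of [fit_single_phase()] results (at least 5).
#' @return A list with `vm_on_tau` (slope, intercept, r_squared, p) and
#'   `cor_f0_tau`, `cor_f0_vm` (estimate + p each).
#' @export
parameter_relations <- function(fits) {
  if (length(fits) < 5L) stop_validation("need at least 5 fits")
  tau <- vapply(fits, `[[`, numeric(1), "tau")
  vm <- vapply(fits, `[[`, numeric(1), "v_m")
  f0 <- vapply(fits, `[[`, numeric(1), "f0")
  if (stats::sd(tau) == 0) stop_validation("constant predictor tau")
  lmfit <- stats::lm(vm ~ tau)
  sm <- summary(lmfit)
  ctau <- stats::cor.test(f0, tau)
  cvm <- stats::cor.test(f0, vm)
  list(
    vm_on_tau = list(slope = unname(stats::coef(lmfit)[2]),
                     intercept = unname(stats::coef(lmfit)[1]),
                     r_squared = sm$r.squared,
                     p = sm$coefficients[2, 4]),
    cor_f0_tau = list(r = unname(ctau$estimate), p = ctau$p.value),
    cor_f0_vm = list(r = unname(cvm$estimate), p = cvm$p.value))
}
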