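# Cross-correlation between binned firing rate and speed: truncated-overlap
# Pearson correlation per lag, peak statistics (r_max, optimal lag, plateau,
# FWHM), and a circular-shift permutation null.

#' Bin a spike train and speed trace into paired series
#'
#' Firing series: spike counts per bin divided by the bin width. Speed
#' series: mean `|speed|` per bin. An optional centered moving average
#' (`smooth_bins` bins wide) is applied to both series, mirroring the curve
#' smoothing used before correlation analysis of recordings; it is symmetric,
#' so it does not bias the lag estimate.
#'
#' @param spikes A [spike_train()].
#' @param speed A [speed_trace()].
#' @param bin Bin width in seconds (default 0.1).
#' @param smooth_bins Moving-average width in bins; 1 disables smoothing
#'   (default 1).
#' @return A list with `firing`, `speed` (equal-length numeric series),
#'   `counts` (raw per-bin spike counts), `bin`.
#' @export
bin_rate_and_speed <- function(spikes, speed, bin = 0.1, smooth_bins = 1) {
  stopifnot(inherits(spikes, "spike_train"), inherits(speed, "speed_trace"))
  if (bin <= 0) stop_validation("bin must be positive")
  dur <- min(spikes$session_duration, speed_duration(speed))
  nb <- floor(dur / bin)
  if (nb < 2L) stop_validation("session too short to bin")
  rel <- spikes$spike_times - speed$t0
  rel <- rel[rel >= 0 & rel < nb * bin]
  counts <- tabulate(floor(rel / bin) + 1L, nbins = nb)
  firing <- counts / bin
  idx <- floor((seq_along(speed$samples) - 1L) / (speed$sampling_rate * bin)) + 1L
  keep <- idx <= nb
  sp <- vapply(split(abs(speed$samples[keep]), idx[keep]), mean, numeric(1))
  sp <- as.numeric(sp)
  if (smooth_bins > 1L) {
    firing <- moving_average(firing, smooth_bins)
    sp <- moving_average(sp, smooth_bins)
  }
  list(firing = firing, speed = sp, counts = counts, bin = bin)
}

# Pearson correlation at every lag -L..L (bins) over the truncated overlap.
# Positive lag pairs firing(t) with speed(t + lag): firing leads speed.
# Uses an FFT for the lagged cross products and cumulative sums for the
# segment moments; zero-variance segments yield NA.
ccf_core <- function(f, s, L) {
  n <- length(f)
  stopifnot(length(s) == n, n > 2L * L)
  cross_all <- stats::convolve(f, s, type = "open")  # cross_all[n - k] = sum f_i s_{i+k}
  ks <- (-L):L
  m <- n - abs(ks)
  Ff <- cumsum(f); Ff2 <- cumsum(f^2)
  Fs <- cumsum(s); Fs2 <- cumsum(s^2)
  sum_head <- function(cs, len) cs[len]                    # sum over 1..len
  sum_tail <- function(cs, k) cs[n] - (if (k > 0) cs[k] else 0)  # sum over (k+1)..n
  sf <- sf2 <- ss <- ss2 <- numeric(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    if (k >= 0) {           # f[1..n-k] with s[(1+k)..n]
      sf[j] <- sum_head(Ff, n - k);  sf2[j] <- sum_head(Ff2, n - k)
      ss[j] <- sum_tail(Fs, k);      ss2[j] <- sum_tail(Fs2, k)
    } else {                # f[(1-k)..n] with s[1..(n+k)]
      sf[j] <- sum_tail(Ff, -k);     sf2[j] <- sum_tail(Ff2, -k)
      ss[j] <- sum_head(Fs, n + k);  ss2[j] <- sum_head(Fs2, n + k)
    }
  }
  cr <- cross_all[n - ks]
  cov <- cr - sf * ss / m
  vf <- sf2 - sf^2 / m
  vs <- ss2 - ss^2 / m
  r <- cov / sqrt(vf * vs)
  r[vf <= 0 | vs <= 0] <- NA_real_
  # Numerical guard: clamp tiny overshoots beyond |1|.
  pmin(pmax(r, -1), 1)
}

#' Cross-correlation function between firing rate and speed
#'
#' Computes the Pearson correlation of `firing(t)` with `speed(t + lag)` over
#' the truncated overlapping segment at every lag on the grid
#' `seq(-lag_max, lag_max, by = bin)` (201 lags for the defaults). Positive
#' lags mean firing leads speed.
#'
#' @param firing,speed Equal-length numeric series on a common `bin` grid
#'   (see [bin_rate_and_speed()]).
#' @param lag_max Maximum lag in seconds (default 10).
#' @param bin Bin width in seconds (default 0.1).
#' @param plateau_tol Tolerance in r units for the peak plateau
#'   (default 1e-3).
#' @return An object of class `ccf_result` with fields `lags`, `r`, `r_max`,
#'   `lag_star`, `plateau`, `fwhm`, `p_perm` (NA until
#'   [permutation_test()] is run).
#' @export
cross_correlation <- function(firing, speed, lag_max = 10, bin = 0.1,
                              plateau_tol = 1e-3) {
  L <- round(lag_max / bin)
  if (length(firing) <= 2L * L) {
    stop_validation("series too short for lag range (need > %d bins)", 2L * L)
  }
  r <- ccf_core(firing, speed, L)
  lags <- ((-L):L) * bin
  ps <- peak_stats(lags, r, plateau_tol = plateau_tol)
  structure(
    c(list(lags = lags, r = r), ps, list(p_perm = NA_real_, significant = NA)),
    class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> r_max = %.3f at lag* = %.2f s (plateau [%.2f, %.2f] s, FWHM = %.2f s)",
              x$r_max, x$lag_star, x$plateau[1], x$plateau[2], x$fwhm))
  if (is.finite(x$p_perm)) cat(sprintf(", p_perm = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' Peak statistics of a correlation-versus-lag curve
#'
#' `r_max` is the maximum correlation; the plateau is the contiguous lag range
#' around the maximum where `r >= r_max - plateau_tol`; the optimal lag is the
#' plateau midpoint; the FWHM is the width of the contiguous region around the
#' peak where `r` exceeds `(r_max + r_floor)/2`, with `r_floor` the minimum
#' observed correlation on the grid and the crossing points located by linear
#' interpolation.
#'
#' @param lags Lag grid in seconds.
#' @param r Correlation per lag (NA allowed).
#' @param plateau_tol Plateau tolerance in r units (default 1e-3).
#' @return A list with `r_max`, `lag_star`, `plateau` (length-2 vector),
#'   `fwhm`.
#' @export
peak_stats <- function(lags, r, plateau_tol = 1e-3) {
  ok <- is.finite(r)
  if (!any(ok)) stop_validation("all correlations undefined")
  r_max <- max(r[ok])
  imax <- which(ok & r == r_max)[1]
  # Plateau: contiguous run through imax with r >= r_max - tol.
  near <- ok & r >= r_max - plateau_tol
  lo <- imax; hi <- imax
  while (lo > 1L && near[lo - 1L]) lo <- lo - 1L
  while (hi < length(r) && near[hi + 1L]) hi <- hi + 1L
  plateau <- c(lags[lo], lags[hi])
  lag_star <- mean(plateau)
  # FWHM around the peak, floored at the minimum observed r.
  r_floor <- min(r[ok])
  half <- (r_max + r_floor) / 2
  above <- ok & r >= half
  a <- imax; b <- imax
  while (a > 1L && above[a - 1L]) a <- a - 1L
  while (b < length(r) && above[b + 1L]) b <- b + 1L
  left <- if (a > 1L && is.finite(r[a - 1L])) {
    lags[a - 1L] + (lags[a] - lags[a - 1L]) * (half - r[a - 1L]) / (r[a] - r[a - 1L])
  } else lags[a]
  right <- if (b < length(r) && is.finite(r[b + 1L])) {
    lags[b] + (lags[b + 1L] - lags[b]) * (r[b] - half) / (r[b] - r[b + 1L])
  } else lags[b]
  list(r_max = r_max, lag_star = lag_star, plateau = plateau,
       fwhm = right - left)
}

# Circular correlation curve: r_circ[m + 1] is the Pearson correlation of
# f(t) with s(t + m mod n) over the full circle, for m = 0..n-1. One FFT
# product yields every circular lag at once.
circular_ccf <- function(f, s) {
  n <- length(f)
  sf <- stats::sd(f) * sqrt((n - 1) / n)
  ss <- stats::sd(s) * sqrt((n - 1) / n)
  if (sf == 0 || ss == 0) stop_validation("zero-variance series")
  cross <- Re(stats::fft(Conj(stats::fft(f)) * stats::fft(s),
                         inverse = TRUE)) / n
  (cross / n - mean(f) * mean(s)) / (sf * ss)
}

#' Circular-shift permutation test for the CCF peak
#'
#' The null distribution of `|r_max|` is generated by circularly shifting the
#' speed series by uniform random offsets of at least `lag_max` (so no null
#' shift recreates near-alignment) and recomputing the maximum absolute
#' correlation over the same `[-lag_max, lag_max]` lag grid. Both the observed
#' and the null statistic are computed on the circular correlation (every lag
#' pairs all `n` samples); circular shifts then form a group, the observed
#' alignment is exchangeable with the shifted ones under independence, and the
#' test is calibrated. The p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)`; significance is declared when
#' the observed `|r_max|` exceeds the 95th percentile of the null.
#'
#' @param firing,speed Equal-length series on the `bin` grid.
#' @param lag_max,bin Lag range and bin width in seconds.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @return A list with `p_perm`, `significant`, `observed_rmax`, `null_rmax`.
#' @export
permutation_test <- function(firing, speed, lag_max = 10, bin = 0.1,
                             n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop_validation("n_perm must be >= 100")
  L <- round(lag_max / bin)
  n <- length(firing)
  if (n <= 2L * L) stop_validation("series too short for lag range")
  if (n - 2L * L - 1L < 1L) stop_validation("series too short for minimum shift")
  r_circ <- circular_ccf(firing, speed)
  win_max <- function(center) {
    idx <- ((center - L):(center + L)) %% n + 1L
    max(abs(r_circ[idx]))
  }
  obs <- win_max(0L)
  with_seed(seed, {
    # Offsets exceed lag_max on both sides of the circle, so no null window
    # contains the zero-lag alignment.
    shifts <- sample.int(n - 2L * L - 1L, n_perm, replace = TRUE) + L
    null_rmax <- vapply(shifts, win_max, numeric(1))
    p <- (1 + sum(null_rmax >= obs)) / (1 + n_perm)
    list(p_perm = p,
         significant = obs > stats::quantile(null_rmax, 0.95, names = FALSE),
         observed_rmax = obs, null_rmax = null_rmax)
  })
}
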