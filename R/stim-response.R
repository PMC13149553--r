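# Optogenetic stimulation analysis: per-trial peak speed and behaviour,
# block-averaged dose-response fitting, frequency-to-firing-rate conversion,
# and latency curves.

#' Extract peak speed, behaviour and latency for one stimulation trial
#'
#' During the stimulation window, the peak is the maximum `|speed|`; its sign
#' classifies the behaviour (positive = running, negative = backing away), and
#' the latency is the first threshold crossing after onset. If `|speed|`
#' never reaches the threshold during stimulation the trial is classified as
#' stopping. The rebound peak is the maximum `|speed|` in the post-offset
#' window, with its own latency measured from stimulus offset.
#'
#' @param speed A [speed_trace()] covering the stimulus and the post window.
#' @param onset,duration Stimulus onset and duration, seconds.
#' @param threshold Movement gate, cm/s (default 0.5).
#' @param rebound_window Post-offset window, seconds (default 10).
#' @return A list with `peak_speed` (signed), `behaviour` (`"running"`,
#'   `"backing_away"` or `"stopping"`), `latency` (NA for stopping),
#'   `rebound_peak`, `rebound_latency`.
#' @export
extract_peak_speed <- function(speed, onset, duration, threshold = 0.5,
                               rebound_window = 10) {
  stopifnot(inherits(speed, "speed_trace"))
  tt <- speed_times(speed)
  offset <- onset + duration
  if (onset < tt[1] || offset + rebound_window > tt[length(tt)] + 1e-9) {
    stop_validation("stimulus window extends past the speed trace")
  }
  during <- which(tt >= onset & tt < offset)
  post <- which(tt >= offset & tt <= offset + rebound_window)
  v_dur <- speed$samples[during]
  amax <- max(abs(v_dur))
  if (amax <= threshold) {
    behaviour <- "stopping"
    peak <- v_dur[which.max(abs(v_dur))]
    latency <- NA_real_
  } else {
    i <- which.max(abs(v_dur))
    peak <- v_dur[i]
    behaviour <- if (peak >= 0) "running" else "backing_away"
    cross <- which(abs(v_dur) > threshold)[1]
    latency <- tt[during[cross]] - onset
  }
  v_post <- speed$samples[post]
  rebound_peak <- max(abs(v_post))
  rb_cross <- which(abs(v_post) > threshold)[1]
  rebound_latency <- if (is.na(rb_cross)) NA_real_ else tt[post[rb_cross]] - offset
  list(peak_speed = peak, behaviour = behaviour, latency = latency,
       rebound_peak = rebound_peak, rebound_latency = rebound_latency)
}

#' Block-average an optogenetic trial table
#'
#' Groups each frequency's trials (in trial order) into blocks of
#' `block_size` and returns the mean peak-speed magnitude per block — the
#' "every 10 trials" averaging of the dose-response analysis. Partial blocks
#' are kept and flagged.
#'
#' @param table An opto trial table (see [generate_optostim_trials()]): data
#'   frame with `frequency`, `trial_index`, `peak_speed`.
#' @param block_size Trials per block (default 10).
#' @return A data frame with `frequency`, `block`, `mean_speed` (magnitude),
#'   `n`, `partial`.
#' @export
block_average <- function(table, block_size = 10) {
  if (!nrow(table)) stop_validation("empty trial table")
  if (block_size < 1) stop_validation("block_size must be >= 1")
  out <- lapply(split(table, table$frequency), function(d) {
    d <- d[order(d$trial_index), , drop = FALSE]
    blk <- (seq_len(nrow(d)) - 1L) %/% block_size + 1L
    agg <- lapply(split(seq_len(nrow(d)), blk), function(idx) {
      data.frame(frequency = d$frequency[1], block = blk[idx[1]],
                 mean_speed = mean(abs(d$peak_speed[idx])),
                 n = length(idx), partial = length(idx) < block_size)
    })
    do.call(rbind, agg)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$frequency, out$block), , drop = FALSE]
}

#' Fit the running-stimulation dose-response curve
#'
#' Single-phase association fit with stimulation frequency as the abscissa:
#' `v = v_m (1 - exp(-(F - f0_stim)/tau_s))`. The frequency offset `f0_stim`
#' is bounded to `[0, min frequency]`.
#'
#' @param frequency Stimulation frequencies, Hz (at least 5 distinct).
#' @param speed Mean peak speeds (magnitudes), cm/s.
#' @return An object of class `stim_fit` with `v_m`, `tau_s`, `f0_stim`,
#'   `r_squared`, `fit_p`, `n_points`, `converged`.
#' @export
fit_stimulation_curve <- function(frequency, speed) {
  res <- .fit_single_phase(frequency, speed, f0_lower = 0,
                           f0_upper = min(frequency))
  structure(
    list(v_m = unname(res$coef["v_m"]), tau_s = unname(res$coef["tau"]),
         f0_stim = unname(res$coef["f0"]), r_squared = res$r_squared,
         fit_p = res$fit_p, n_points = res$n_points,
         converged = res$converged),
    class = "stim_fit")
}

#' @export
print.stim_fit <- function(x, ...) {
  cat(sprintf("<stim_fit> v_m = %.2f cm/s, tau_s = %.2f Hz, f0 = %.2f Hz (R2 = %.3f)\n",
              x$v_m, x$tau_s, x$f0_stim, x$r_squared))
  invisible(x)
}

#' Linear frequency-to-firing-rate conversion and cross-synaptic ratio
#'
#' Evoked firing rates increase linearly with stimulation frequency; this
#' fits an ordinary least-squares slope per neuron class and reports the
#' ratio of the direct-response slope to the trans-synaptic slope (the drive
#' required upstream per downstream spike).
#'
#' @param rates Data frame with columns `class`, `frequency`, `rate`
#'   (spikes/s); at least 3 frequencies per class.
#' @param direct_class,trans_class Class labels entering the ratio; defaults
#'   to the first two classes in the table.
#' @return A list with `slopes` (named, spikes/s per Hz), `intercepts`, and
#'   `ratio` = `slopes[direct_class] / slopes[trans_class]`.
#' @export
freq_to_rate_conversion <- function(rates, direct_class = NULL,
                                    trans_class = NULL) {
  classes <- unique(rates$class)
  slopes <- intercepts <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    d <- rates[rates$class == cl, , drop = FALSE]
    if (length(unique(d$frequency)) < 3L) {
      stop_validation("class '%s': need at least 3 frequencies", cl)
    }
    cf <- stats::coef(stats::lm(rate ~ frequency, data = d))
    slopes[cl] <- cf[["frequency"]]
    intercepts[cl] <- cf[["(Intercept)"]]
  }
  direct_class <- direct_class %||% classes[1]
  trans_class <- trans_class %||% classes[min(2L, length(classes))]
  list(slopes = slopes, intercepts = intercepts,
       ratio = unname(slopes[direct_class] / slopes[trans_class]))
}

#' Latency versus frequency and versus converted speed
#'
#' Means the per-trial running latencies by frequency and, using a fitted
#' dose-response curve, converts each frequency into its predicted running
#' speed so latency can be compared across groups on a common behavioural
#' abscissa. Reports the Spearman correlation of latency with frequency as a
#' monotonicity diagnostic.
#'
#' @param table An opto trial table with `frequency`, `latency`, `behaviour`.
#' @param stim_fit A [fit_stimulation_curve()] result.
#' @return A list with `curve` (data frame: `frequency`, `mean_latency`, `n`,
#'   `converted_speed`) and `spearman_rho`.
#' @export
latency_curves <- function(table, stim_fit) {
  stopifnot(inherits(stim_fit, "stim_fit"))
  d <- table[is.finite(table$latency), , drop = FALSE]
  if (!nrow(d)) stop_validation("no defined latencies")
  agg <- lapply(split(d, d$frequency), function(g) {
    data.frame(frequency = g$frequency[1], mean_latency = mean(g$latency),
               n = nrow(g))
  })
  curve <- do.call(rbind, agg)
  rownames(curve) <- NULL
  if (nrow(curve) < 3L) stop_validation("latencies defined for fewer than 3 frequencies")
  curve <- curve[order(curve$frequency), , drop = FALSE]
  curve$converted_speed <- single_phase(curve$frequency, stim_fit$f0_stim,
                                        stim_fit$v_m, stim_fit$tau_s)
  rho <- suppressWarnings(
    stats::cor(curve$frequency, curve$mean_latency, method = "spearman"))
  list(curve = curve, spearman_rho = rho)
}
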