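# Event detection, trial labelling, peri-event binning, spike-density
# estimation, firing-window detection, and heatmap construction.

#' Detect running events from a speed trace
#'
#' A running onset is the first sample at which `|speed|` strictly exceeds the
#' threshold; the event ends at the first subsequent sample where `|speed|`
#' stays below threshold for at least `min_gap` seconds. Sub-threshold dips
#' shorter than `min_gap` are bridged, and events shorter than `min_duration`
#' are dropped.
#'
#' @param speed A [speed_trace()].
#' @param threshold Running gate in cm/s (default 0.5).
#' @param min_gap Merge gap in seconds (default 0.5).
#' @param min_duration Minimum event duration in seconds (default 0.5).
#' @return A data frame of class `running_events` with columns `onset`,
#'   `offset`, `peak_speed`, `provenance` (initially `"spontaneous"`).
#' @export
detect_running_events <- function(speed, threshold = 0.5, min_gap = 0.5,
                                  min_duration = 0.5) {
  stopifnot(inherits(speed, "speed_trace"))
  x <- abs(speed$samples)
  fs <- speed$sampling_rate
  above <- x > threshold
  empty <- structure(
    data.frame(onset = numeric(), offset = numeric(), peak_speed = numeric(),
               provenance = character(), stringsAsFactors = FALSE),
    class = c("running_events", "data.frame"))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # Bridge sub-min_gap dips between consecutive supra-threshold runs.
  gap_samples <- min_gap * fs
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < gap_samples) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  dur <- (merged$end - merged$start + 1L) / fs
  merged <- merged[dur >= min_duration, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  tt <- speed_times(speed)
  structure(
    data.frame(
      onset = tt[merged$start],
      offset = tt[merged$end],
      peak_speed = vapply(seq_len(nrow(merged)), function(i) {
        max(x[merged$start[i]:merged$end[i]])
      }, numeric(1)),
      provenance = "spontaneous", stringsAsFactors = FALSE),
    class = c("running_events", "data.frame")
  )
}

#' Label running events and stimulus trials
#'
#' A running onset is spontaneous iff no stimulus onset falls within the
#' preceding `sensory_running_window`; otherwise it is stimulus-evoked. A
#' stimulus is a no-run trial iff `|speed|` stays below the running gate
#' throughout its post-stimulus window.
#'
#' @param events A [detect_running_events()] result.
#' @param stimuli A [stimulus_schedule()].
#' @param speed A [speed_trace()].
#' @param sensory_running_window Window in seconds.
#' @param threshold Running gate in cm/s.
#' @return A list with `events` (provenance filled in) and `stimuli` (the
#'   schedule with a logical `no_run` column).
#' @export
label_trials <- function(events, stimuli, speed, sensory_running_window = 3,
                         threshold = 0.5) {
  if (sensory_running_window <= 0) stop_validation("window must be > 0")
  if (nrow(events)) {
    evoked <- vapply(events$onset, function(on) {
      any(stimuli$onset >= on - sensory_running_window & stimuli$onset < on)
    }, logical(1))
    events$provenance <- ifelse(evoked, "stimulus_evoked", "spontaneous")
  }
  stimuli <- as.data.frame(stimuli)
  if (nrow(stimuli)) {
    tt <- speed_times(speed)
    x <- abs(speed$samples)
    stimuli$no_run <- vapply(seq_len(nrow(stimuli)), function(k) {
      w <- tt >= stimuli$onset[k] &
        tt <= stimuli$onset[k] + sensory_running_window
      !any(x[w] > threshold)
    }, logical(1))
  } else {
    stimuli$no_run <- logical(0)
  }
  list(events = events, stimuli = stimuli)
}

#' Compute a peri-event time histogram
#'
#' Bins spikes relative to each alignment event with half-open bins
#' `[edge, edge + bin_width)`; a spike exactly at the event belongs to the
#' first post-event bin. The mean rate in bin j is
#' `sum_i counts[i, j] / (n_trials * bin_width)`.
#'
#' @param spikes A [spike_train()].
#' @param event_times Alignment event times, seconds.
#' @param window Two-element vector `c(pre, post)` in seconds relative to the
#'   event (pre typically negative).
#' @param bin_width Bin width in seconds.
#' @return An object of class `peth` with fields `bin_edges`, `counts`
#'   (trials x bins), `n_trials`, `bin_width`, `mean_rate`.
#' @export
compute_peth <- function(spikes, event_times, window, bin_width) {
  stopifnot(inherits(spikes, "spike_train"))
  if (bin_width <= 0) stop_validation("bin_width must be positive")
  if (!length(event_times)) stop_validation("no alignment events")
  edges <- seq(window[1], window[2], by = bin_width)
  nb <- length(edges) - 1L
  counts <- matrix(0L, nrow = length(event_times), ncol = nb)
  for (i in seq_along(event_times)) {
    rel <- spikes$spike_times - event_times[i]
    rel <- rel[rel >= window[1] & rel < window[1] + nb * bin_width]
    if (length(rel)) {
      j <- floor((rel - window[1]) / bin_width) + 1L
      tab <- tabulate(j, nbins = nb)
      counts[i, ] <- tab
    }
  }
  structure(
    list(bin_edges = edges, counts = counts, n_trials = length(event_times),
         bin_width = bin_width,
         mean_rate = colSums(counts) / (length(event_times) * bin_width),
         alignment = "event"),
    class = "peth"
  )
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d trials x %d bins (bin %g s), window [%g, %g] s\n",
              x$n_trials, ncol(x$counts), x$bin_width,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' Gaussian-kernel spike density function
#'
#' Sums a Gaussian kernel of SD `sigma` centred on each spike, giving a
#' continuous rate estimate whose integral equals the spike count (up to
#' boundary truncation).
#'
#' @param spikes A [spike_train()].
#' @param sigma Kernel SD in seconds (default 0.010).
#' @param grid Evaluation times in seconds; defaults to the whole session at
#'   1-ms resolution.
#' @return An object of class `spike_density` with fields `grid`, `density`,
#'   `sigma`.
#' @export
spike_density <- function(spikes, sigma = 0.010, grid = NULL) {
  stopifnot(inherits(spikes, "spike_train"))
  if (sigma <= 0) stop_validation("sigma must be positive")
  if (is.null(grid)) grid <- seq(0, spikes$session_duration, by = 0.001)
  dens <- numeric(length(grid))
  # Each spike only contributes within ~6 sigma; chunk to keep memory flat.
  for (t_k in spikes$spike_times) {
    lo <- findInterval(t_k - 6 * sigma, grid)
    hi <- findInterval(t_k + 6 * sigma, grid) + 1L
    lo <- max(lo, 1L); hi <- min(hi, length(grid))
    idx <- lo:hi
    dens[idx] <- dens[idx] + stats::dnorm(grid[idx], mean = t_k, sd = sigma)
  }
  structure(list(grid = grid, density = dens, sigma = sigma),
            class = "spike_density")
}

#' Detect the firing-running time window from a PETH
#'
#' The window start is the left edge of the first bin whose mean rate exceeds
#' `baseline mean + 2 * baseline SD`; under the default `"sustained"` rule the
#' crossing must hold in every bin from there until running onset (time 0),
#' under `"single"` the first crossing bin anywhere in the pre-onset span
#' starts the window. The window always ends at onset.
#'
#' @param peth A [compute_peth()] result aligned to running onset, covering
#'   the baseline period and the pre-onset span.
#' @param baseline_period Two-element vector in seconds (default `c(-10, -5)`)
#'   that must precede the analysis span.
#' @param rule `"sustained"` or `"single"`.
#' @return An object of class `firing_window` with fields `start`, `end` (0),
#'   `baseline_mean`, `baseline_sd`, `crossed`, `degenerate`.
#' @export
detect_firing_window <- function(peth, baseline_period = c(-10, -5),
                                 rule = c("sustained", "single")) {
  rule <- match.arg(rule)
  stopifnot(inherits(peth, "peth"))
  left <- peth$bin_edges[-length(peth$bin_edges)]
  base_idx <- left >= baseline_period[1] & left < baseline_period[2]
  if (!any(base_idx)) stop_validation("PETH does not cover the baseline period")
  base <- peth$mean_rate[base_idx]
  bm <- mean(base)
  bs <- stats::sd(base)
  degenerate <- !is.finite(bs) || bs == 0
  thr <- bm + 2 * (if (degenerate) 0 else bs)
  span <- which(left >= baseline_period[2] & left < 0)
  no_window <- structure(
    list(start = NA_real_, end = 0, baseline_mean = bm, baseline_sd = bs,
         crossed = FALSE, degenerate = degenerate),
    class = "firing_window")
  if (!length(span)) return(no_window)
  over <- peth$mean_rate[span] > thr
  if (!any(over)) return(no_window)
  if (rule == "sustained") {
    # Contiguous run of supra-threshold bins ending at onset.
    if (!over[length(over)]) return(no_window)
    k <- length(over)
    while (k > 1L && over[k - 1L]) k <- k - 1L
    start <- left[span[k]]
  } else {
    start <- left[span[which(over)[1]]]
  }
  structure(
    list(start = start, end = 0, baseline_mean = bm, baseline_sd = bs,
         crossed = TRUE, degenerate = degenerate),
    class = "firing_window")
}

#' Summarise firing-to-running-onset time differences
#'
#' The per-neuron time difference is `-start` of its firing window. With at
#' least `min_fit` values, a Gaussian `A exp(-(x - mu)^2 / (2 sd^2))` is
#' fitted to the histogram by least squares and its R-squared reported.
#'
#' @param windows A list of [detect_firing_window()] results, or a numeric
#'   vector of time differences in seconds.
#' @param n_bins Histogram bin count (default `max(8, ceiling(sqrt(n)))`).
#' @param min_fit Minimum sample size for the Gaussian fit (default 3).
#' @return A list with `differences`, `mean`, `sd`, `n`, `histogram`
#'   (mids/density), and `fit` (`mu`, `sigma`, `amplitude`, `r_squared`), or
#'   `fit = NULL` when too few values.
#' @export
time_difference_stats <- function(windows, n_bins = NULL, min_fit = 3) {
  diffs <- if (is.numeric(windows)) {
    windows
  } else {
    vals <- vapply(windows, function(w) -w$start, numeric(1))
    vals[!is.na(vals)]
  }
  n <- length(diffs)
  out <- list(differences = diffs, mean = mean(diffs), sd = stats::sd(diffs),
              n = n, histogram = NULL, fit = NULL)
  if (n < min_fit || length(unique(diffs)) < 2L) return(out)
  if (is.null(n_bins)) n_bins <- max(8L, ceiling(sqrt(n)))
  h <- graphics::hist(diffs, breaks = n_bins, plot = FALSE)
  out$histogram <- list(mids = h$mids, density = h$density)
  x <- h$mids; y <- h$density
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sg^2)),
      start = list(A = max(y), mu = mean(diffs), sg = max(stats::sd(diffs), 1e-3)),
      lower = c(A = 0, mu = -Inf, sg = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    res <- y - stats::predict(m)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    cf <- stats::coef(m)
    list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sg"])),
         amplitude = unname(cf["A"]), r_squared = r2)
  }, error = function(e) NULL)
  out$fit <- fit
  out
}

#' Build a min-max scaled population heatmap around running onsets
#'
#' For each neuron, running events qualify only if no other running event
#' occurred within the 10 s preceding the onset and the event's peak speed
#' reaches the running gate. Rates in 0.1-s bins over a +/- 10 s window are
#' computed as `count / (n_trials * bin_width)` and each neuron's row is
#' min-max scaled to [0, 1]; constant rows map to 0.
#'
#' @param sess A [session()].
#' @param events A [detect_running_events()] result (optionally labelled);
#'   computed from the session's speed trace when `NULL`.
#' @param bin_width Heatmap bin width, seconds (default 0.1).
#' @param window Half-width of the peri-onset window, seconds (default 10).
#' @param exclusion Pre-onset exclusion span, seconds (default 10).
#' @param threshold Running gate, cm/s (default 0.5).
#' @return A numeric matrix (neurons x bins) with an attribute `bin_edges`;
#'   neurons with zero qualifying events are omitted with a warning and listed
#'   in attribute `dropped`.
#' @export
build_heatmap <- function(sess, events = NULL, bin_width = 0.1, window = 10,
                          exclusion = 10, threshold = 0.5) {
  stopifnot(inherits(sess, "session"))
  if (is.null(events)) events <- detect_running_events(sess$speed, threshold)
  qual <- .qualifying_events(events, exclusion, threshold)
  dur <- speed_duration(sess$speed)
  # Keep events whose full window lies inside the recording.
  qual <- qual[qual$onset - window >= 0 & qual$onset + window <= dur, ,
               drop = FALSE]
  rows <- list(); dropped <- character()
  edges <- NULL
  for (st in sess$spike_trains) {
    if (!nrow(qual)) {
      dropped <- c(dropped, st$neuron_id); next
    }
    p <- compute_peth(st, qual$onset, window = c(-window, window),
                      bin_width = bin_width)
    edges <- p$bin_edges
    r <- p$mean_rate
    rng <- range(r)
    rows[[st$neuron_id]] <- if (rng[2] > rng[1]) {
      (r - rng[1]) / (rng[2] - rng[1])
    } else {
      rep(0, length(r))
    }
  }
  if (length(dropped)) {
    warning(sprintf("neurons with zero qualifying events omitted: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(), nrow = 0, ncol = 0)
  attr(m, "bin_edges") <- edges
  attr(m, "dropped") <- dropped
  m
}

.qualifying_events <- function(events, exclusion, threshold) {
  if (!nrow(events)) return(events)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    on <- events$onset[i]
    prior <- events$onset < on & events$offset > on - exclusion
    events$peak_speed[i] >= threshold && !any(prior)
  }, logical(1))
  events[keep, , drop = FALSE]
}
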