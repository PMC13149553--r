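# Two-stage functional classification: sensory-responsive, running-related,
# and R-neurons (running-correlated, stimulus-insensitive).

#' Paired one-sided test for a post-stimulus firing-rate increase
#'
#' Wilcoxon signed-rank test of the per-trial mean rate in the 1-s
#' post-stimulus response window against the 1-s pre-stimulus baseline,
#' one-sided for an increase.
#'
#' @param post_rates,baseline_rates Per-trial rates, spikes/s (paired).
#' @param alpha Significance level (default 0.05).
#' @return A list with `flag`, `p`, `n`.
#' @export
sensory_response_test <- function(post_rates, baseline_rates, alpha = 0.05) {
  .paired_increase_test(post_rates, baseline_rates, alpha)
}

#' Paired one-sided test for elevated pre-running firing
#'
#' Wilcoxon signed-rank test of the per-trial rate in the designated
#' pre-running window against the stationary baseline, one-sided for an
#' increase.
#'
#' @param pre_running_rates,baseline_rates Per-trial rates, spikes/s (paired).
#' @param alpha Significance level (default 0.05).
#' @return A list with `flag`, `p`, `n`.
#' @export
running_related_test <- function(pre_running_rates, baseline_rates,
                                 alpha = 0.05) {
  .paired_increase_test(pre_running_rates, baseline_rates, alpha)
}

.paired_increase_test <- function(a, b, alpha) {
  stopifnot(length(a) == length(b))
  d <- a - b
  if (!length(d) || all(d == 0)) {
    return(list(flag = FALSE, p = 1, n = length(d)))
  }
  p <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  )
  list(flag = is.finite(p) && p < alpha, p = p, n = length(d))
}

#' Classify one neuron as sensory-responsive, running-related, or R-neuron
#'
#' Stage one tests, per modality, whether the mean rate in the `[0, 1]` s
#' post-stimulus window of no-run trials exceeds the 1-s pre-stimulus
#' baseline. Stage two tests whether the rate in the neuron's pre-running
#' window (its detected firing window when available, else the configured
#' default) exceeds the stationary baseline across spontaneous runs. A neuron
#' is an R-neuron iff it is running-related and responsive to no modality.
#'
#' The neuron-level "sensory-responsive" call tests three modalities at once;
#' by default the three p-values are Holm-adjusted so that the family-wise
#' error of the at-least-one-modality call stays at `alpha` (an uncorrected
#' per-modality call at `alpha` would wrongly exclude roughly `3 * alpha` of
#' true running-correlated neurons). Set
#' `modality_correction = "none"` for uncorrected per-modality calls.
#'
#' @param sess A [session()].
#' @param neuron_id Which neuron to classify.
#' @param config An [analysis_config()].
#' @param labelled Optional precomputed [label_trials()] result (recomputed
#'   otherwise).
#' @param modality_correction `"holm"` (default) or `"none"`: multiplicity
#'   handling across the three sensory modalities for the neuron-level call.
#' @return An object of class `neuron_label` with per-modality flags and
#'   p-values, the running flag and p-value, `is_R_neuron`, the attached
#'   `firing_window`, and an `indeterminate` reason when trial counts are too
#'   low.
#' @export
classify_neuron <- function(sess, neuron_id, config = analysis_config(),
                            labelled = NULL,
                            modality_correction = c("holm", "none")) {
  modality_correction <- match.arg(modality_correction)
  stopifnot(inherits(sess, "session"))
  st <- sess$spike_trains[[neuron_id]]
  if (is.null(st)) stop_validation("unknown neuron id '%s'", neuron_id)
  if (is.null(labelled)) {
    ev <- detect_running_events(sess$speed, threshold = config$run_threshold,
                                min_gap = config$min_gap,
                                min_duration = config$min_duration)
    labelled <- label_trials(ev, sess$stimuli, sess$speed,
                             sensory_running_window = config$sensory_running_window,
                             threshold = config$run_threshold)
  }
  modalities <- c("sound", "light", "air_puff")
  sens <- stats::setNames(vector("list", length(modalities)), modalities)
  indeterminate <- character()
  for (m in modalities) {
    stim <- labelled$stimuli
    rows <- stim[stim$modality == m & stim$no_run, , drop = FALSE]
    if (nrow(rows) < config$min_trials) {
      if (any(stim$modality == m)) {
        indeterminate <- c(indeterminate,
                           sprintf("too few no-run %s trials", m))
      }
      sens[[m]] <- list(flag = NA, p = NA_real_, n = nrow(rows))
      next
    }
    post <- .window_rates(st, rows$onset, c(0, 1))
    base <- .window_rates(st, rows$onset, c(-1, 0))
    sens[[m]] <- sensory_response_test(post, base, alpha = config$alpha)
  }
  ps <- vapply(sens, function(s) s$p, numeric(1))
  tested <- is.finite(ps)
  p_adj <- ps
  if (modality_correction == "holm" && any(tested)) {
    p_adj[tested] <- stats::p.adjust(ps[tested], method = "holm")
  }
  for (m in names(sens)) sens[[m]]$p_adjusted <- p_adj[[m]]
  sensory_responsive <- any(tested & p_adj < config$alpha)

  spont <- labelled$events[labelled$events$provenance == "spontaneous", ,
                           drop = FALSE]
  window <- NULL
  run <- list(flag = NA, p = NA_real_, n = nrow(spont))
  if (nrow(spont) < config$min_trials) {
    indeterminate <- c(indeterminate, "too few spontaneous runs")
  } else {
    peth <- compute_peth(st, spont$onset,
                         window = c(config$baseline_period[1], 1),
                         bin_width = config$heatmap_bin)
    window <- detect_firing_window(peth,
                                   baseline_period = config$baseline_period,
                                   rule = config$window_rule)
    pre_win <- if (isTRUE(window$crossed)) {
      c(window$start, 0)
    } else {
      config$pre_run_window
    }
    pre <- .window_rates(st, spont$onset, pre_win)
    base <- .window_rates(st, spont$onset, config$baseline_period)
    run <- running_related_test(pre, base, alpha = config$alpha)
  }
  running_related <- isTRUE(run$flag)
  is_R <- running_related && !sensory_responsive &&
    !length(indeterminate)
  structure(
    list(neuron_id = neuron_id,
         sensory = sens,
         sensory_responsive = sensory_responsive,
         running_related = running_related,
         running_p = run$p,
         is_R_neuron = is_R,
         firing_window = window,
         indeterminate = indeterminate),
    class = "neuron_label")
}

#' @export
print.neuron_label <- function(x, ...) {
  cat(sprintf("<neuron_label> %s: sensory=%s running=%s R-neuron=%s\n",
              x$neuron_id, x$sensory_responsive, x$running_related,
              x$is_R_neuron))
  if (length(x$indeterminate)) {
    cat("  indeterminate:", paste(x$indeterminate, collapse = "; "), "\n")
  }
  invisible(x)
}

# Per-trial mean rate of `st` in `win` (seconds relative to each event).
.window_rates <- function(st, event_times, win) {
  span <- diff(win)
  vapply(event_times, function(e) {
    sum(st$spike_times >= e + win[1] & st$spike_times < e + win[2]) / span
  }, numeric(1))
}
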