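# Core data model: spike trains, speed traces, stimulus schedules, sessions,
# analysis configuration, and columnar text readers/writers.

#' Construct a spike train
#'
#' A spike train holds the sorted spike times of one neuron over one recording
#' session, in session-relative seconds (0 = recording start).
#'
#' @param neuron_id Character scalar identifying the neuron.
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, session_duration]`.
#' @param session_duration Session length in seconds.
#' @param region Anatomical label, one of `"TeA"`, `"dPAG"`, `"SC"`, `"other"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(neuron_id, spike_times, session_duration,
                        region = c("other", "TeA", "dPAG", "SC")) {
  region <- match.arg(region)
  if (!is.character(neuron_id) || length(neuron_id) != 1L) {
    stop_validation("neuron_id must be a single string")
  }
  spike_times <- as.numeric(spike_times)
  if (!is_scalar_number(session_duration) || session_duration <= 0) {
    stop_validation("session_duration must be a positive number")
  }
  if (length(spike_times)) {
    if (any(!is.finite(spike_times))) {
      stop_validation("spike train '%s': non-finite spike times", neuron_id)
    }
    if (any(diff(spike_times) <= 0)) {
      stop_validation("spike train '%s': spike times must be strictly increasing",
                      neuron_id)
    }
    if (spike_times[1L] < 0 || spike_times[length(spike_times)] > session_duration) {
      stop_validation("spike train '%s': spike times outside [0, %g] s",
                      neuron_id, session_duration)
    }
  }
  structure(
    list(neuron_id = neuron_id, spike_times = spike_times,
         session_duration = session_duration, region = region),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s): %d spikes over %.1f s\n",
              x$neuron_id, x$region, length(x$spike_times), x$session_duration))
  invisible(x)
}

#' Construct a uniformly sampled speed trace
#'
#' Speed is signed: positive samples are forward running, negative samples are
#' backing away. Analyses that the encoding model defines on "speed" use the
#' magnitude `|v|`.
#'
#' @param samples Numeric vector of speed samples in cm/s.
#' @param sampling_rate Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `speed_trace`.
#' @export
speed_trace <- function(samples, sampling_rate, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    stop_validation("sampling_rate must be a positive number")
  }
  if (any(!is.finite(samples))) stop_validation("speed samples must be finite")
  structure(
    list(samples = samples, sampling_rate = sampling_rate, t0 = t0),
    class = "speed_trace"
  )
}

#' @export
print.speed_trace <- function(x, ...) {
  cat(sprintf("<speed_trace> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$t0))
  invisible(x)
}

#' Time axis of a speed trace
#' @param speed A `speed_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
speed_times <- function(speed) {
  speed$t0 + (seq_along(speed$samples) - 1L) / speed$sampling_rate
}

#' Duration covered by a speed trace, in seconds
#' @param speed A `speed_trace`.
#' @export
speed_duration <- function(speed) length(speed$samples) / speed$sampling_rate

#' Construct a stimulus schedule
#'
#' @param modality Character vector: `"sound"`, `"light"`, `"air_puff"` or
#'   `"opto"`.
#' @param onset Onset times in seconds, non-decreasing.
#' @param duration Durations in seconds, positive.
#' @param opto_frequency Optogenetic pulse frequency in Hz; must be present
#'   (non-`NA`) exactly for rows with modality `"opto"`.
#' @return A data frame of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(modality = character(), onset = numeric(),
                              duration = numeric(), opto_frequency = NULL) {
  n <- length(onset)
  if (is.null(opto_frequency)) opto_frequency <- rep(NA_real_, n)
  if (length(modality) != n || length(duration) != n ||
      length(opto_frequency) != n) {
    stop_validation("stimulus schedule columns must have equal length")
  }
  ok <- modality %in% c("sound", "light", "air_puff", "opto")
  if (!all(ok)) stop_validation("unknown stimulus modality: %s",
                                paste(unique(modality[!ok]), collapse = ", "))
  if (n && any(diff(onset) < 0)) stop_validation("stimulus onsets must be non-decreasing")
  if (any(duration <= 0)) stop_validation("stimulus durations must be positive")
  is_opto <- modality == "opto"
  if (any(is_opto & !is.finite(opto_frequency)) ||
      any(!is_opto & is.finite(opto_frequency))) {
    stop_validation("opto_frequency must be given exactly for opto events")
  }
  structure(
    data.frame(modality = modality, onset = onset, duration = duration,
               opto_frequency = opto_frequency, stringsAsFactors = FALSE),
    class = c("stimulus_schedule", "data.frame")
  )
}

#' Construct a recording session
#'
#' @param spike_trains List of [spike_train()] objects.
#' @param speed A [speed_trace()].
#' @param stimuli A [stimulus_schedule()] (may be empty).
#' @param metadata Free-form named list of labels.
#' @return An object of class `session`.
#' @export
session <- function(spike_trains, speed, stimuli = stimulus_schedule(),
                    metadata = list()) {
  if (inherits(spike_trains, "spike_train")) spike_trains <- list(spike_trains)
  stopifnot(inherits(speed, "speed_trace"), inherits(stimuli, "stimulus_schedule"))
  dur <- speed_duration(speed)
  for (st in spike_trains) {
    if (!inherits(st, "spike_train")) stop_validation("spike_trains must be spike_train objects")
    if (abs(st$session_duration - dur) > 1 / speed$sampling_rate + 1e-9) {
      stop_validation("spike train '%s' duration (%g s) inconsistent with speed trace (%g s)",
                      st$neuron_id, st$session_duration, dur)
    }
  }
  ids <- vapply(spike_trains, `[[`, character(1), "neuron_id")
  if (anyDuplicated(ids)) stop_validation("duplicate neuron ids in session")
  names(spike_trains) <- ids
  structure(
    list(spike_trains = spike_trains, speed = speed, stimuli = stimuli,
         metadata = metadata),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %d neurons, %.1f s, %d stimulus events\n",
              length(x$spike_trains), speed_duration(x$speed), nrow(x$stimuli)))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the fixed constants of the pipeline. Defaults follow the recording
#' analysis conventions: running gated at 0.5 cm/s, 10 ms PSTH bins, 0.1 s
#' heatmap and CCF bins, a Gaussian spike-density kernel of sigma = 10 ms,
#' a [-10, 10] s CCF lag range and 1000 circular-shift permutations.
#'
#' @param run_threshold Running gate in cm/s (default 0.5).
#' @param psth_bin PSTH/PETH bin width in seconds (default 0.010).
#' @param heatmap_bin Heatmap bin width in seconds (default 0.1).
#' @param sdf_sigma Spike-density Gaussian sigma in seconds (default 0.010).
#' @param ccf_lag_max Maximum CCF lag in seconds (default 10).
#' @param ccf_bin CCF bin width in seconds (default 0.1).
#' @param ccf_smooth_bins Width (in CCF bins) of the centered moving average
#'   applied to both the binned firing-rate and speed series before
#'   correlation; 1 disables smoothing (default 11, i.e. 1.1 s).
#' @param n_permutations Circular-shift permutations for the CCF null
#'   (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param sensory_running_window Seconds separating a stimulus from a
#'   subsequent running onset for the run to count as stimulus-evoked, and the
#'   post-stimulus span checked for absence of running (default 3; the study
#'   takes this window from prior work without printing a value, so it is a
#'   required, overridable setting).
#' @param baseline_period Two-element vector, seconds relative to running
#'   onset, used as the stationary baseline for PETH thresholding and the
#'   running-related test (default `c(-10, -5)`).
#' @param pre_run_window Fallback pre-running analysis window, seconds relative
#'   to onset, used when a neuron has no detected firing window
#'   (default `c(-2, 0)`).
#' @param window_rule `"sustained"` (crossing must hold until onset) or
#'   `"single"` (first crossing bin) for the firing-window definition.
#' @param min_gap,min_duration Running-event merge gap and minimum duration in
#'   seconds (defaults 0.5 and 0.5).
#' @param min_trials Minimum paired trials for the rank tests (default 5).
#' @param resample_hz Common grid for internal speed resampling (default 100).
#' @param plateau_tol Tolerance in r units defining the CCF peak plateau
#'   (default 1e-3).
#' @param rng_seed Integer seed making the pipeline deterministic.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(run_threshold = 0.5,
                            psth_bin = 0.010,
                            heatmap_bin = 0.1,
                            sdf_sigma = 0.010,
                            ccf_lag_max = 10,
                            ccf_bin = 0.1,
                            ccf_smooth_bins = 11,
                            n_permutations = 1000,
                            alpha = 0.05,
                            sensory_running_window = 3,
                            baseline_period = c(-10, -5),
                            pre_run_window = c(-2, 0),
                            window_rule = c("sustained", "single"),
                            min_gap = 0.5,
                            min_duration = 0.5,
                            min_trials = 5,
                            resample_hz = 100,
                            plateau_tol = 1e-3,
                            rng_seed = 1L) {
  window_rule <- match.arg(window_rule)
  cfg <- list(run_threshold = run_threshold, psth_bin = psth_bin,
              heatmap_bin = heatmap_bin, sdf_sigma = sdf_sigma,
              ccf_lag_max = ccf_lag_max, ccf_bin = ccf_bin,
              ccf_smooth_bins = ccf_smooth_bins,
              n_permutations = n_permutations, alpha = alpha,
              sensory_running_window = sensory_running_window,
              baseline_period = baseline_period,
              pre_run_window = pre_run_window,
              window_rule = window_rule,
              min_gap = min_gap, min_duration = min_duration,
              min_trials = min_trials, resample_hz = resample_hz,
              plateau_tol = plateau_tol, rng_seed = as.integer(rng_seed))
  for (nm in c("run_threshold", "psth_bin", "heatmap_bin", "sdf_sigma",
               "ccf_lag_max", "ccf_bin", "n_permutations",
               "sensory_running_window", "min_gap", "min_duration",
               "min_trials", "resample_hz", "plateau_tol")) {
    if (!is_scalar_number(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop_validation("config field '%s' must be a positive number", nm)
    }
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must lie in (0, 1)")
  }
  structure(cfg, class = "analysis_config")
}

#' Read or write an analysis configuration as YAML-like text
#'
#' The configuration file is a flat `key: value` document; every default of
#' [analysis_config()] can be overridden.
#'
#' @param path File path.
#' @param config An `analysis_config` (for writing).
#' @return `read_config()` returns an `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop_validation("malformed config line: '%s'", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "window_rule") {
      args[[key]] <- val
    } else {
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (any(is.na(num))) stop_validation("non-numeric config value for '%s'", key)
      args[[key]] <- num
    }
  }
  do.call(analysis_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  lines <- vapply(names(config), function(nm) {
    val <- config[[nm]]
    sprintf("%s: %s", nm, paste(format(val, scientific = FALSE), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop_validation("cannot parse %s: %s", path, conditionMessage(e))
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_validation("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  }
  df
}

#' Read a session from columnar text files
#'
#' Expects three tab-separated files: spikes (`neuron_id`, `spike_time_s`),
#' speed (`time_s`, `speed_cm_s`) and stimuli (`modality`, `onset_s`,
#' `duration_s`, `opto_freq_hz`; the last may be empty). The speed trace is
#' validated for uniform sampling and resampled by linear interpolation onto
#' the common analysis grid (`config$resample_hz`).
#'
#' @param spike_file,speed_file,stim_file File paths; `stim_file` may be
#'   `NULL` for a session without stimuli.
#' @param config An [analysis_config()].
#' @param neuron_ids Optional character vector declaring the full set of
#'   neurons; neurons listed but absent from the spike file get empty trains.
#' @param regions Optional named character vector mapping neuron id to region.
#' @return A validated [session()].
#' @export
read_session <- function(spike_file, speed_file, stim_file = NULL,
                         config = analysis_config(), neuron_ids = NULL,
                         regions = NULL) {
  sp <- .read_tsv(spike_file, c("neuron_id", "spike_time_s"))
  spd <- .read_tsv(speed_file, c("time_s", "speed_cm_s"))
  if (!is.numeric(spd$time_s) || !is.numeric(spd$speed_cm_s)) {
    bad <- which(is.na(suppressWarnings(as.numeric(spd$time_s))) |
                   is.na(suppressWarnings(as.numeric(spd$speed_cm_s))))[1]
    stop_validation("%s: malformed row %d", speed_file, (bad %||% 1L) + 1L)
  }
  if (nrow(spd) < 2L) stop_validation("speed trace needs at least 2 samples")
  dts <- diff(spd$time_s)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 0.01 * dt)) {
    stop_validation("speed timestamps are not uniformly sampled")
  }
  # Resample onto the common analysis grid.
  fs <- config$resample_hz
  t0 <- spd$time_s[1]
  t_end <- spd$time_s[nrow(spd)]
  grid <- seq(t0, t_end, by = 1 / fs)
  v <- stats::approx(spd$time_s, spd$speed_cm_s, xout = grid, rule = 2)$y
  speed <- speed_trace(v, sampling_rate = fs, t0 = t0)
  dur <- speed_duration(speed)

  if (nrow(sp) && (!is.numeric(sp$spike_time_s) || any(is.na(sp$spike_time_s)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(sp$spike_time_s))))[1]
    stop_validation("%s: malformed row %d", spike_file, (bad %||% 1L) + 1L)
  }
  ids <- unique(c(as.character(sp$neuron_id), neuron_ids))
  trains <- lapply(ids, function(id) {
    times <- sp$spike_time_s[sp$neuron_id == id]
    region <- if (!is.null(regions) && id %in% names(regions)) regions[[id]] else "other"
    spike_train(id, times, session_duration = dur, region = region)
  })

  stimuli <- stimulus_schedule()
  if (!is.null(stim_file)) {
    stdf <- .read_tsv(stim_file, c("modality", "onset_s", "duration_s"))
    freq <- if ("opto_freq_hz" %in% names(stdf)) {
      suppressWarnings(as.numeric(stdf$opto_freq_hz))
    } else rep(NA_real_, nrow(stdf))
    stimuli <- stimulus_schedule(as.character(stdf$modality), stdf$onset_s,
                                 stdf$duration_s, freq)
  }
  session(trains, speed, stimuli,
          metadata = list(spike_file = spike_file, speed_file = speed_file))
}

#' Write a session to columnar text files
#'
#' Inverse of [read_session()]; writes `spikes.tsv`, `speed.tsv` and
#' `stimuli.tsv` into `dir`.
#'
#' @param sess A [session()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_session <- function(sess, dir) {
  stopifnot(inherits(sess, "session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spikes = file.path(dir, "spikes.tsv"),
             speed = file.path(dir, "speed.tsv"),
             stimuli = file.path(dir, "stimuli.tsv"))
  sp <- do.call(rbind, lapply(sess$spike_trains, function(st) {
    if (!length(st$spike_times)) return(NULL)
    data.frame(neuron_id = st$neuron_id,
               spike_time_s = sprintf("%.6f", st$spike_times))
  }))
  if (is.null(sp)) sp <- data.frame(neuron_id = character(), spike_time_s = character())
  utils::write.table(sp, paths["spikes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spd <- data.frame(time_s = sprintf("%.6f", speed_times(sess$speed)),
                    speed_cm_s = sprintf("%.6f", sess$speed$samples))
  utils::write.table(spd, paths["speed"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stdf <- data.frame(modality = sess$stimuli$modality,
                     onset_s = sess$stimuli$onset,
                     duration_s = sess$stimuli$duration,
                     opto_freq_hz = sess$stimuli$opto_frequency)
  utils::write.table(stdf, paths["stimuli"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(paths)
}

#' Write pipeline results as structured text
#'
#' Serializes any pipeline output (per-neuron reports, CCF results, encoding
#' fits, ...) to JSON, embedding a snapshot of the configuration and seed so
#' results are self-describing and re-readable with [read_results()].
#'
#' @param results Any serializable pipeline output.
#' @param path Output file path.
#' @param config Optional [analysis_config()] snapshot to embed.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, config = NULL) {
  payload <- list(
    package = "speedenc",
    config = if (!is.null(config)) unclass(config),
    results = strip_classes(results)
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) stop_validation("cannot write results to %s: %s",
                                         path, conditionMessage(e)))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Drop S3 classes recursively so jsonlite serializes plain structures.
strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
    x
  } else {
    if (is.data.frame(x)) class(x) <- "data.frame"
    x
  }
}

#' Run the full per-neuron analysis pipeline
#'
#' For each neuron in the session: detects running events, labels trials,
#' classifies the neuron (sensory-responsive / running-related / R-neuron) and,
#' for R-neurons, estimates the firing-speed cross-correlation with its
#' permutation null, aligns firing to speed at the optimal lag, and fits the
#' single-phase association model alongside a linear comparison. The pipeline
#' is a pure function of `(session, config)` including `config$rng_seed`.
#'
#' @param sess A [session()].
#' @param config An [analysis_config()].
#' @return A list of class `pipeline_report`: one entry per neuron with fields
#'   `neuron_id`, `status`, `label`, `firing_window`, `ccf`, `fit`,
#'   `linear_comparison`.
#' @export
run_pipeline <- function(sess, config = analysis_config()) {
  stopifnot(inherits(sess, "session"), inherits(config, "analysis_config"))
  events <- detect_running_events(sess$speed, threshold = config$run_threshold,
                                  min_gap = config$min_gap,
                                  min_duration = config$min_duration)
  lab <- label_trials(events, sess$stimuli, sess$speed,
                      sensory_running_window = config$sensory_running_window,
                      threshold = config$run_threshold)
  reports <- vector("list", length(sess$spike_trains))
  names(reports) <- names(sess$spike_trains)
  for (i in seq_along(sess$spike_trains)) {
    st <- sess$spike_trains[[i]]
    rep_i <- tryCatch(
      .analyse_neuron(st, sess, config, lab,
                      seed = derive_seed(config$rng_seed, i)),
      error = function(e) {
        list(neuron_id = st$neuron_id, status = "error",
             message = sprintf("neuron %s: %s", st$neuron_id,
                               conditionMessage(e)))
      }
    )
    reports[[i]] <- rep_i
  }
  structure(reports, class = "pipeline_report")
}

.analyse_neuron <- function(st, sess, config, lab, seed) {
  spont <- lab$events[lab$events$provenance == "spontaneous", , drop = FALSE]
  if (nrow(spont) < config$min_trials) {
    return(list(neuron_id = st$neuron_id, status = "insufficient running events",
                n_spontaneous_runs = nrow(spont)))
  }
  label <- classify_neuron(sess, st$neuron_id, config, labelled = lab)
  out <- list(neuron_id = st$neuron_id, status = "ok", label = label,
              firing_window = label$firing_window)
  if (isTRUE(label$is_R_neuron)) {
    series <- bin_rate_and_speed(st, sess$speed, bin = config$ccf_bin,
                                 smooth_bins = config$ccf_smooth_bins)
    ccf <- cross_correlation(series$firing, series$speed,
                             lag_max = config$ccf_lag_max, bin = config$ccf_bin,
                             plateau_tol = config$plateau_tol)
    perm <- permutation_test(series$firing, series$speed,
                             lag_max = config$ccf_lag_max, bin = config$ccf_bin,
                             n_perm = config$n_permutations, seed = seed)
    ccf$p_perm <- perm$p_perm
    ccf$significant <- perm$significant
    pairs <- align_by_lag(series$firing, series$speed, ccf$lag_star,
                          bin = config$ccf_bin)
    fit <- fit_single_phase(pairs$f, pairs$v)
    cmp <- fit_linear_and_compare(pairs$f, pairs$v, fit)
    out$ccf <- ccf[c("r_max", "lag_star", "plateau", "fwhm", "p_perm",
                     "significant")]
    out$fit <- fit
    out$linear_comparison <- cmp
  }
  out
}
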