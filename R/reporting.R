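# Population summaries and evaluation of pipeline output against synthetic
# ground truth.

#' Population summary of classification, CCF and encoding-fit results
#'
#' Assembles the figure-equivalent population tables: distributions of
#' `r_max`, optimal lag and fit R-squared with least-squares Gaussian fits
#' (the same machinery as [time_difference_stats()]).
#'
#' @param reports A [run_pipeline()] result, or a plain list of per-neuron
#'   reports.
#' @return A list with `n_neurons`, `n_R_neurons`, and for each of `r_max`,
#'   `lag_star`, `fit_r_squared` a summary (`mean`, `sd`, `n`, Gaussian
#'   `fit`).
#' @export
population_summary <- function(reports) {
  ok <- Filter(function(r) identical(r$status, "ok"), reports)
  rn <- Filter(function(r) isTRUE(r$label$is_R_neuron), ok)
  pull <- function(get) {
    vals <- vapply(rn, function(r) {
      v <- get(r)
      if (is.null(v) || !is.finite(v)) NA_real_ else v
    }, numeric(1))
    vals[!is.na(vals)]
  }
  summarise <- function(vals) {
    if (!length(vals)) return(list(n = 0L, mean = NA_real_, sd = NA_real_,
                                   fit = NULL))
    s <- time_difference_stats(vals)
    list(n = s$n, mean = s$mean, sd = s$sd, fit = s$fit)
  }
  list(
    n_neurons = length(reports),
    n_R_neurons = length(rn),
    r_max = summarise(pull(function(r) r$ccf$r_max)),
    lag_star = summarise(pull(function(r) r$ccf$lag_star)),
    fit_r_squared = summarise(pull(function(r) r$fit$r_squared)))
}

#' Evaluate pipeline output against synthetic ground truth
#'
#' Compares R-neuron detection with the generator's labels (confusion
#' counts, sensitivity, specificity), summarizes parameter-recovery errors
#' for detected true R-neurons (bias and median absolute relative error of
#' `f0`, `tau_f`, `v_m`; lag-recovery error from the CCF optimal lag), and
#' reports the permutation rejection rate within the unrelated (null) class.
#'
#' @param reports A [run_pipeline()] result on a synthetic session.
#' @param truth The `truth` data frame from
#'   [generate_population_session()].
#' @return An object of class `evaluation_report`.
#' @export
evaluate_against_truth <- function(reports, truth) {
  ids <- vapply(reports, `[[`, character(1), "neuron_id")
  if (!setequal(ids, truth$neuron_id)) {
    stop_validation("report and truth neuron ids do not match")
  }
  truth <- truth[match(ids, truth$neuron_id), , drop = FALSE]
  called_R <- vapply(reports, function(r) {
    identical(r$status, "ok") && isTRUE(r$label$is_R_neuron)
  }, logical(1))
  is_R <- truth$class == "R_neuron"
  tp <- sum(called_R & is_R); fn <- sum(!called_R & is_R)
  fp <- sum(called_R & !is_R); tn <- sum(!called_R & !is_R)

  rel_err <- function(est, tru) (est - tru) / tru
  rows <- which(called_R & is_R)
  par_rec <- NULL
  if (length(rows)) {
    get <- function(i, field) {
      v <- reports[[i]]$fit[[field]]
      if (is.null(v)) NA_real_ else v
    }
    err <- data.frame(
      f0 = vapply(rows, function(i) get(i, "f0"), numeric(1)) - truth$f0[rows],
      tau = rel_err(vapply(rows, function(i) get(i, "tau"), numeric(1)),
                    truth$tau_f[rows]),
      v_m = rel_err(vapply(rows, function(i) get(i, "v_m"), numeric(1)),
                    truth$v_m[rows]),
      lag = vapply(rows, function(i) {
        v <- reports[[i]]$ccf$lag_star
        if (is.null(v)) NA_real_ else v
      }, numeric(1)) - truth$lag[rows])
    par_rec <- list(
      f0_bias = mean(err$f0, na.rm = TRUE),
      tau_bias = mean(err$tau, na.rm = TRUE),
      tau_medare = stats::median(abs(err$tau), na.rm = TRUE),
      vm_bias = mean(err$v_m, na.rm = TRUE),
      vm_medare = stats::median(abs(err$v_m), na.rm = TRUE),
      lag_bias = mean(err$lag, na.rm = TRUE),
      lag_mad = stats::median(abs(err$lag), na.rm = TRUE),
      lag_errors = err$lag)
  }
  null_rows <- which(truth$class == "unrelated")
  sig <- vapply(null_rows, function(i) {
    r <- reports[[i]]
    if (identical(r$status, "ok") && !is.null(r$ccf)) {
      isTRUE(r$ccf$significant)
    } else NA
  }, logical(1))
  structure(
    list(confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         parameter_recovery = par_rec,
         null_rejection_rate = if (any(!is.na(sig))) {
           mean(sig, na.rm = TRUE)
         } else NA_real_),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<evaluation_report> R-neuron detection: TP=%d FP=%d FN=%d TN=%d\n",
              cm["tp"], cm["fp"], cm["fn"], cm["tn"]))
  cat(sprintf("  sensitivity = %.3f, specificity = %.3f\n",
              x$sensitivity, x$specificity))
  if (!is.null(x$parameter_recovery)) {
    pr <- x$parameter_recovery
    cat(sprintf("  tau medARE = %.3f, v_m medARE = %.3f, lag MAD = %.3f s\n",
                pr$tau_medare, pr$vm_medare, pr$lag_mad))
  }
  invisible(x)
}
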