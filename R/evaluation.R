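#' Seizure sensitivity
#'
#' Fraction of test seizures preceded by a valid alarm (or, in
#' forecasting mode, whose onset falls inside a warning).
#'
#' @param predicted Logical (or 0/1) vector, one element per test
#'   seizure.
#' @return Fraction in `[0, 1]`.
#' @export
seizure_sensitivity <- function(predicted) {
  if (length(predicted) == 0) stop("at least one test seizure is required")
  mean(as.logical(predicted))
}

#' False-positive rate per hour
#'
#' Number of false alarms divided by the interictal duration with the
#' alarms' refractory time excluded from the denominator.
#'
#' @param n_false Number of false alarms.
#' @param interictal_h Interictal duration in hours.
#' @param refractory_h Refractory time (hours) overlapping the
#'   interictal period.
#' @return False alarms per hour.
#' @export
fpr_per_hour <- function(n_false, interictal_h, refractory_h = 0) {
  den <- interictal_h - refractory_h
  if (den <= 0) stop("no interictal time left after refractory exclusion")
  n_false / den
}

#' Warning timeline and time under warning
#'
#' In forecasting mode a window is under a high seizure-risk warning
#' when its Firing Power reaches the alarm threshold. Time under warning
#' (TiW) is the number of warning windows times the window length.
#'
#' @param fp Firing Power vector.
#' @param threshold Warning threshold (default 0.7).
#' @return Logical per-window warning vector.
#' @export
warning_timeline_from_fp <- function(fp, threshold = 0.7) {
  as.logical(fp >= threshold)
}

#' @rdname warning_timeline_from_fp
#' @param warnings Logical per-window warning vector.
#' @param window_s Window length in seconds.
#' @return `time_in_warning`: hours under warning.
#' @export
time_in_warning <- function(warnings, window_s = 5) {
  sum(warnings) * window_s / 3600
}

#' Surrogate-onset significance test
#'
#' Tests whether the observed seizure sensitivity beats chance by
#' Monte-Carlo relocation of the test onsets: each draw moves every
#' onset uniformly within its own contiguous seizure-data span (leaving
#' room for the SPH + SOP window before it), re-classifies the fixed
#' alarm times, and recomputes sensitivity. The model and its alarms are
#' never touched. The p-value is the add-one empirical tail
#' `p = (1 + #{SS_surr >= SS_obs}) / (n + 1)`; the model performs above
#' chance when `p < alpha`.
#'
#' @param alarm_times_s Fixed alarm times (seconds).
#' @param onsets_s Observed test onsets (seconds), one per span.
#' @param spans Data frame with columns `start`, `end`: the contiguous
#'   recording block containing each test seizure.
#' @param sph_min,sop_min Horizon parameters (minutes).
#' @param n_surrogates Number of Monte-Carlo draws (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `sz_surrogate`: `observed_ss`,
#'   `surrogate_ss` (vector), `p_value`, `above_chance`, `alpha`.
#' @export
surrogate_test <- function(alarm_times_s, onsets_s, spans, sph_min = 10,
                           sop_min, n_surrogates = 1000, alpha = 0.05,
                           seed = 1) {
  stopifnot(nrow(spans) == length(onsets_s), n_surrogates >= 1)
  lo <- spans$start + (sph_min + sop_min) * 60
  hi <- spans$end
  bad <- which(lo >= hi)
  if (length(bad) > 0) {
    stop("seizure-data span ", bad[1],
         " too short for any valid onset relocation")
  }
  obs <- seizure_sensitivity(
    classify_alarms(alarm_times_s, onsets_s, sph_min, sop_min)$predicted)
  surr <- withr::with_seed(derive_seed(seed, 77), {
    vapply(seq_len(n_surrogates), function(i) {
      o <- sort(runif(length(onsets_s), lo, hi))
      seizure_sensitivity(
        classify_alarms(alarm_times_s, o, sph_min, sop_min)$predicted)
    }, numeric(1))
  })
  p <- (1 + sum(surr >= obs)) / (n_surrogates + 1)
  structure(list(observed_ss = obs, surrogate_ss = surr, p_value = p,
                 above_chance = p < alpha, alpha = alpha,
                 n_surrogates = n_surrogates),
            class = "sz_surrogate")
}

#' @export
print.sz_surrogate <- function(x, ...) {
  cat(sprintf(
    "<surrogate test> observed SS %.3f, surrogate mean %.3f, p = %.4f (%s chance at alpha = %g)\n",
    x$observed_ss, mean(x$surrogate_ss), x$p_value,
    if (x$above_chance) "above" else "not above", x$alpha))
  invisible(x)
}

#' Circadian forecasting baseline
#'
#' Raises a high seizure-risk warning every day from `half_width_min`
#' minutes before to `half_width_min` minutes after each training-onset
#' time of day; overlapping warning intervals merge. The baseline uses
#' circadian information only — no EEG.
#'
#' @param train_onsets `POSIXct` training seizure onsets (their times of
#'   day define the daily warnings).
#' @param window_start `POSIXct` window grid of the test span.
#' @param half_width_min Warning half-width in minutes (default 30).
#' @return Logical per-window warning vector (a window is warned when
#'   its start lies in a warning interval, half-open on the right).
#' @export
circadian_forecast <- function(train_onsets, window_start,
                               half_width_min = 30) {
  if (length(train_onsets) == 0) stop("at least one training onset needed")
  tod_w <- as.numeric(window_start) %% 86400
  warn <- rep(FALSE, length(tod_w))
  hw <- half_width_min * 60
  for (t in as.numeric(train_onsets) %% 86400) {
    warn <- warn | (((tod_w - (t - hw)) %% 86400) < 2 * hw)
  }
  warn
}

#' Compare an EEG-based forecaster with the circadian baseline
#'
#' Computes forecasting-mode seizure sensitivity (onset falls inside a
#' warned window — no prediction horizon in forecasting mode) and time
#' under warning for two warning timelines on a common window grid, and
#' flags whether the first forecaster dominates (strictly higher SS and
#' strictly lower TiW).
#'
#' @param warn_a,warn_b Logical warning vectors on the same grid
#'   (e.g. EEG-based and circadian).
#' @param window_start_s Window start times (seconds).
#' @param window_s Window length (seconds).
#' @param onsets_s Test onsets (seconds).
#' @param labels Names of the two forecasters.
#' @return A data frame with one row per forecaster (`ss`, `tiw_h`,
#'   `n_seizures`) and attribute `a_dominates`.
#' @export
compare_forecasters <- function(warn_a, warn_b, window_start_s, window_s,
                                onsets_s, labels = c("eeg", "circadian")) {
  if (length(warn_a) != length(warn_b) ||
      length(warn_a) != length(window_start_s)) {
    stop("warning timelines must share the window grid")
  }
  hit <- function(warn) {
    vapply(onsets_s, function(o) {
      i <- findInterval(o, window_start_s)
      i >= 1 && i <= length(warn) && warn[i]
    }, logical(1))
  }
  ss_a <- seizure_sensitivity(hit(warn_a))
  ss_b <- seizure_sensitivity(hit(warn_b))
  out <- data.frame(
    forecaster = labels,
    ss = c(ss_a, ss_b),
    tiw_h = c(time_in_warning(warn_a, window_s),
              time_in_warning(warn_b, window_s)),
    n_seizures = length(onsets_s))
  attr(out, "a_dominates") <- ss_a > ss_b && out$tiw_h[1] < out$tiw_h[2]
  out
}

#' One-sided cumulative binomial count test
#'
#' Upper-tail exact binomial probability `P(X >= k | n, p0)`, used to
#' judge whether a count of patients showing some behaviour exceeds what
#' a null proportion `p0` would produce.
#'
#' @param k Observed count.
#' @param n Number of trials.
#' @param p0 Null proportion in (0, 1).
#' @param alpha Significance level (default 0.05).
#' @return A list with `p_value` and `significant`.
#' @export
binomial_count_test <- function(k, n, p0, alpha = 0.05) {
  stopifnot(k >= 0, k <= n, n >= 1)
  if (!(p0 > 0 && p0 < 1)) stop("p0 must be in (0, 1)")
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(p_value = p, significant = p < alpha)
}

#' Evaluate a trained model on the test period
#'
#' Runs the prediction chain on the test feature matrix (binary window
#' outputs, Firing Power over the selected preictal span, 0.7-threshold
#' alarms with a refractory period of the same length, no alarms inside
#' ictal windows) and reports seizure sensitivity, false-positive rate
#' per hour (refractory time excluded from the interictal denominator),
#' time under warning, and optionally the surrogate significance test.
#'
#' @param model A trained `sz_model` (with `preictal_min` set).
#' @param fm_test Test-period `feature_matrix`.
#' @param test_ann Test-seizure [seizure_annotation].
#' @param threshold Alarm threshold.
#' @param sph_min Seizure prediction horizon (minutes).
#' @param surrogates Number of surrogate draws (0 skips the test).
#' @param alpha Surrogate significance level.
#' @param seed Seed for the surrogate draws.
#' @param ictal_s Assumed ictal length when offsets are missing.
#' @return An object of class `sz_evaluation` with fields `ss`, `fpr_h`,
#'   `tiw_h`, `n_test_seizures`, `interictal_h`, `alarms`, `fp`,
#'   `warnings`, and `surrogate` (when requested).
#' @export
evaluate_patient <- function(model, fm_test, test_ann, threshold = 0.7,
                             sph_min = 10, surrogates = 1000,
                             alpha = 0.05, seed = 1, ictal_s = 60) {
  stopifnot(inherits(model, "sz_model"), inherits(fm_test, "feature_matrix"))
  P <- model$preictal_min
  if (is.null(P)) stop("model carries no selected preictal duration")
  t0 <- as.numeric(fm_test$start_time)
  on_s <- as.numeric(test_ann$onset) - t0
  off_s <- if (!is.null(test_ann$offset)) {
    as.numeric(test_ann$offset) - t0
  } else on_s + ictal_s
  fmL <- label_windows(fm_test, test_ann, P, ictal_s = ictal_s)
  w0 <- fm_test$window_start_s
  ictal_mask <- fmL$excluded

  outputs <- predict_windows(model, fm_test)
  ch <- alarm_chain(as.integer(outputs), w0, fm_test$window_s, on_s,
                    preictal_min = P, threshold = threshold,
                    sph_min = sph_min, ictal_mask = ictal_mask)
  n_false <- sum(ch$classified$alarms$kind == "false_positive")
  interictal_w <- sum(fmL$labels == "interictal", na.rm = TRUE)
  refr_interictal_w <- sum(ch$refractory &
                             !is.na(fmL$labels) &
                             fmL$labels == "interictal")
  interictal_h <- interictal_w * fm_test$window_s / 3600
  refr_h <- refr_interictal_w * fm_test$window_s / 3600
  warn <- warning_timeline_from_fp(ch$fp, threshold)

  surro <- NULL
  if (surrogates > 0) {
    blk_start <- c(min(w0), off_s[-length(off_s)])
    spans <- data.frame(start = blk_start, end = on_s)
    surro <- surrogate_test(ch$alarm_times_s, on_s, spans,
                            sph_min = sph_min, sop_min = P,
                            n_surrogates = surrogates, alpha = alpha,
                            seed = seed)
  }
  structure(list(
    ss = seizure_sensitivity(ch$classified$predicted),
    fpr_h = fpr_per_hour(n_false, interictal_h, refr_h),
    tiw_h = time_in_warning(warn, fm_test$window_s),
    n_test_seizures = length(on_s),
    interictal_h = interictal_h - refr_h,
    alarms = ch$classified$alarms, predicted = ch$classified$predicted,
    fp = ch$fp, warnings = warn, refractory = ch$refractory,
    window_start_s = w0, window_s = fm_test$window_s,
    preictal_min = P, surrogate = surro
  ), class = "sz_evaluation")
}

#' @export
print.sz_evaluation <- function(x, ...) {
  cat(sprintf(
    "<evaluation> SS %.2f (%d seizures), FPR/h %.3f over %.1f h, TiW %.2f h\n",
    x$ss, x$n_test_seizures, x$fpr_h, x$interictal_h, x$tiw_h))
  if (!is.null(x$surrogate)) print(x$surrogate)
  invisible(x)
}
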