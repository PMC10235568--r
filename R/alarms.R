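#' Firing Power smoothing of binary window predictions
#'
#' The Firing Power at window n is the mean of the classifier's binary
#' outputs over the last `tau` windows, where `tau` is the number of
#' windows spanning the preictal period; values lie in `[0, 1]`. During
#' warm-up (the first `tau - 1` windows) the partial mean over the
#' available windows is used, and those windows carry a warm-up flag so
#' evaluation can exclude them if configured.
#'
#' @param outputs Binary (0/1) vector of per-window predictions.
#' @param tau Smoothing span in windows (`preictal duration / window
#'   length`); at least 1.
#' @return Numeric vector of Firing Power values with attributes `tau`
#'   and `warmup` (logical vector).
#' @export
firing_power <- function(outputs, tau) {
  stopifnot(tau >= 1, tau == round(tau))
  if (length(outputs) == 0) stop("empty prediction stream")
  if (!all(outputs %in% c(0, 1))) stop("outputs must be binary (0/1)")
  n <- length(outputs)
  cs0 <- c(0, cumsum(outputs))          # cs0[k + 1] = sum of first k outputs
  idx <- seq_len(n)
  span <- pmin(idx, tau)                # partial mean during warm-up
  fp <- (cs0[idx + 1] - cs0[idx - span + 1]) / span
  attr(fp, "tau") <- as.integer(tau)
  attr(fp, "warmup") <- idx < tau
  fp
}

#' Generate alarms from a Firing Power series
#'
#' An alarm is raised at the first window where the Firing Power reaches
#' the threshold outside a refractory span; the refractory period starts
#' at the alarm window and lasts `refractory_windows` windows (equal to
#' the preictal duration by convention). While the series stays above
#' threshold, no further alarm is raised inside the refractory span, but
#' a series still above threshold immediately after the refractory span
#' ends re-alarms at once. Windows flagged as ictal never raise alarms.
#'
#' @param fp Firing Power vector (from [firing_power()]).
#' @param threshold Alarm threshold in (0, 1]; default 0.7.
#' @param refractory_windows Refractory span in windows.
#' @param ictal_mask Optional logical vector; `TRUE` windows cannot raise
#'   alarms.
#' @param warmup `"partial"` (default) lets the partial-mean warm-up
#'   values raise alarms; `"exclude"` suppresses alarms during the
#'   first `tau - 1` windows (appropriate when the series starts
#'   mid-record, e.g. cross-validation folds, where a deployed system
#'   would already hold a full smoothing span of history).
#' @return A list with `alarm_idx` (window indices of alarms) and
#'   `refractory` (logical per-window refractory mask).
#' @export
generate_alarms <- function(fp, threshold = 0.7, refractory_windows,
                            ictal_mask = NULL,
                            warmup = c("partial", "exclude")) {
  stopifnot(threshold > 0, threshold <= 1, refractory_windows >= 1)
  warmup <- match.arg(warmup)
  n <- length(fp)
  if (is.null(ictal_mask)) ictal_mask <- rep(FALSE, n)
  stopifnot(length(ictal_mask) == n)
  if (warmup == "exclude" && !is.null(attr(fp, "warmup"))) {
    ictal_mask <- ictal_mask | attr(fp, "warmup")
  }
  alarm_idx <- integer(0)
  refractory <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (!ictal_mask[i] && fp[i] >= threshold) {
      alarm_idx <- c(alarm_idx, i)
      j <- min(n, i + refractory_windows - 1L)
      refractory[i:j] <- TRUE
      i <- i + as.integer(refractory_windows)
    } else {
      i <- i + 1L
    }
  }
  list(alarm_idx = alarm_idx, refractory = refractory)
}

#' Classify alarms against seizure onsets under an SPH/SOP horizon
#'
#' An alarm is a true positive when some onset lies between
#' `sph_min` and `sop_min` minutes after it (the alarm must lead the
#' onset by at least the seizure prediction horizon, to leave time for
#' intervention, and the seizure must occur within the occurrence
#' period, equal to the preictal duration). Each alarm credits at most
#' one seizure (the earliest eligible onset); a seizure counts as
#' predicted when at least one true-positive alarm targets it.
#'
#' @param alarm_times_s Alarm times in seconds (same clock as onsets).
#' @param onsets_s Sorted seizure onset times in seconds.
#' @param sph_min Seizure prediction horizon in minutes (default 10).
#' @param sop_min Seizure occurrence period bound in minutes (the
#'   selected preictal duration); must exceed `sph_min`.
#' @return A list with `alarms` (data frame: time_s, kind,
#'   matched_onset) and `predicted` (logical per seizure).
#' @export
classify_alarms <- function(alarm_times_s, onsets_s, sph_min = 10,
                            sop_min) {
  stopifnot(sph_min >= 0, sop_min > sph_min)
  if (length(onsets_s) > 1 && any(diff(onsets_s) <= 0)) {
    stop("onsets must be sorted")
  }
  sph <- sph_min * 60; sop <- sop_min * 60
  predicted <- rep(FALSE, length(onsets_s))
  kind <- character(length(alarm_times_s))
  matched <- rep(NA_integer_, length(alarm_times_s))
  for (a in seq_along(alarm_times_s)) {
    lead <- onsets_s - alarm_times_s[a]
    ok <- which(lead >= sph & lead <= sop)
    if (length(ok) > 0) {
      kind[a] <- "true_positive"
      matched[a] <- ok[1]
      predicted[ok[1]] <- TRUE
    } else {
      kind[a] <- "false_positive"
    }
  }
  list(alarms = data.frame(time_s = as.numeric(alarm_times_s),
                           kind = kind, matched_onset = matched),
       predicted = predicted)
}

#' Run the full alarm chain on a prediction stream
#'
#' Convenience wrapper: Firing Power with `tau` windows spanning the
#' preictal duration, alarm generation at the threshold with a
#' refractory period of the same length, and SPH/SOP classification
#' against the onsets.
#'
#' @param outputs Binary per-window predictions.
#' @param window_start_s Window start times in seconds.
#' @param window_s Window length in seconds.
#' @param onsets_s Seizure onset times in seconds.
#' @param preictal_min Preictal duration in minutes (sets `tau`, the
#'   refractory span and the SOP).
#' @param threshold Alarm threshold (default 0.7).
#' @param sph_min Seizure prediction horizon in minutes (default 10).
#' @param ictal_mask Optional logical no-alarm mask.
#' @param warmup Warm-up alarm handling, see [generate_alarms()].
#' @return A list with `fp`, `alarm_idx`, `alarm_times_s`, `refractory`,
#'   `classified` (see [classify_alarms()]) and `tau`.
#' @export
alarm_chain <- function(outputs, window_start_s, window_s, onsets_s,
                        preictal_min, threshold = 0.7, sph_min = 10,
                        ictal_mask = NULL, warmup = "partial") {
  tau <- as.integer(round(preictal_min * 60 / window_s))
  fp <- firing_power(outputs, tau)
  al <- generate_alarms(fp, threshold, refractory_windows = tau,
                        ictal_mask = ictal_mask, warmup = warmup)
  times <- window_start_s[al$alarm_idx]
  cls <- classify_alarms(times, onsets_s, sph_min = sph_min,
                         sop_min = preictal_min)
  list(fp = fp, alarm_idx = al$alarm_idx, alarm_times_s = times,
       refractory = al$refractory, classified = cls, tau = tau)
}
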