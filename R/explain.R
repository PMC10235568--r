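#' Per-feature counterfactual explanations for a linear model
#'
#' For one (raw) feature vector, finds for every feature the slightest
#' change that flips the model's window decision: with a linear margin
#' `m(x) = w'x + b`, moving feature j by `delta_j = -m/w_j` lands on the
#' boundary, and an infinitesimal sign-preserving epsilon crosses it
#' (the margin-zero tie counts as positive, so flipping a positive
#' decision needs the epsilon while flipping a negative one does not).
#' Features with zero weight cannot flip the decision and are reported
#' infeasible. Deltas are given in standardized units and in raw feature
#' units (`delta * train sd`), sorted by increasing magnitude.
#'
#' @param model A logistic `sz_model`.
#' @param x Raw feature vector (named, covering the model's features).
#' @param eps Relative epsilon pushed past the boundary.
#' @return A data frame of class `sz_counterfactuals`: feature,
#'   original (standardized) value, delta (standardized), delta_raw,
#'   flipped prediction, feasible; sorted by `abs(delta)` (infeasible
#'   last).
#' @export
counterfactual_per_feature <- function(model, x, eps = 1e-9) {
  stopifnot(inherits(model, "sz_model"), model$type == "lr")
  X <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (any(!is.finite(x))) stop("non-finite feature values")
  xs <- apply_standardizer(model$standardizer, X)[1, model$selected]
  w <- model$coef
  m <- sum(w * xs) + model$intercept
  pred <- as.integer(m >= 0)
  # boundary shift per feature, with an epsilon past the boundary so the
  # flipped margin is strictly on the other side despite rounding
  # (margin 0 counts as class 1, so flipping 0 -> 1 targets +epsilon)
  target <- (if (pred == 1) -1 else 1) * eps * max(1, abs(m))
  delta <- ifelse(w != 0, (target - m) / w, NA_real_)
  sdv <- model$standardizer$scale[model$selected]
  out <- data.frame(
    feature = model$selected,
    original = unname(xs),
    delta = unname(delta),
    delta_raw = unname(delta * sdv),
    flipped_prediction = 1L - pred,
    feasible = w != 0,
    row.names = NULL)
  out <- out[order(!out$feasible, abs(out$delta)), ]
  rownames(out) <- NULL
  class(out) <- c("sz_counterfactuals", "data.frame")
  out
}

#' Counterfactual search for an SVM voting ensemble
#'
#' Line search for the smallest standardized change of one feature that
#' flips the ensemble's majority vote, scanning outward from zero in
#' both directions over a coarse grid and refining the first flip by
#' bisection. Infeasible when no flip exists within the bounds.
#'
#' @param model An `sz_model` (any type; the search only queries
#'   predictions).
#' @param x Raw feature vector (named).
#' @param feature Feature name to perturb.
#' @param bounds Symmetric standardized search bound (scalar, > 0).
#' @param grid_n Coarse grid points per direction.
#' @param tol Bisection tolerance on the standardized delta.
#' @return One-row data frame: feature, delta (standardized),
#'   delta_raw, flipped prediction, feasible.
#' @export
counterfactual_ensemble <- function(model, x, feature, bounds = 10,
                                    grid_n = 200, tol = 1e-6) {
  stopifnot(inherits(model, "sz_model"), is.finite(bounds), bounds > 0)
  stopifnot(feature %in% model$standardizer$kept)
  sdv <- model$standardizer$scale[[feature]]
  predict_delta <- function(d) {
    X <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
    X[1, feature] <- X[1, feature] + d * sdv
    as.integer(predict_windows(model, X))
  }
  base <- predict_delta(0)
  best <- NA_real_
  for (sgn in c(1, -1)) {
    dg <- sgn * seq(0, bounds, length.out = grid_n + 1)[-1]
    flips <- vapply(dg, function(d) predict_delta(d) != base, logical(1))
    if (!any(flips)) next
    k <- which(flips)[1]
    lo <- if (k == 1) 0 else dg[k - 1]
    hi <- dg[k]
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      if (predict_delta(mid) != base) hi <- mid else lo <- mid
    }
    if (is.na(best) || abs(hi) < abs(best)) best <- hi
  }
  data.frame(feature = feature,
             delta = best, delta_raw = best * sdv,
             flipped_prediction = 1L - base,
             feasible = !is.na(best))
}

#' Single-feature-group ablation retraining
#'
#' Hypothesis-testing explanation: the model is retrained once per
#' feature group (e.g. only delta-band powers, only gamma-band powers,
#' only the signal variance), with the identical split, labelling,
#' balancing and seed, and the Firing Power traces of all retrained
#' models are emitted on the test grid next to the original model's
#' trace. Comparing which restricted models reproduce the original
#' alarm dynamics localizes the discriminative information.
#'
#' @param fm_train Labelled training `feature_matrix`.
#' @param fm_test Test `feature_matrix`.
#' @param groups Named list; each element selects features by regular
#'   expression(s) matched against the full `channel/feature` names.
#'   See [ablation_groups()] for the standard band-power set.
#' @param model Base model type (default `"lr"`, as used for this
#'   analysis).
#' @param seed Master seed shared by all retrained models.
#' @param include_original Also emit the full-feature model's trace.
#' @param ... Passed to [train_patient_model()].
#' @return A list with `fp` (windows x groups matrix of Firing Power
#'   traces), `models` and `tau`.
#' @export
single_feature_retrain <- function(fm_train, fm_test, groups,
                                   model = "lr", seed = 1,
                                   include_original = TRUE, ...) {
  stopifnot(inherits(fm_train, "feature_matrix"),
            inherits(fm_test, "feature_matrix"))
  P <- fm_train$preictal_min
  if (is.null(P)) stop("training features must be labelled (preictal_min)")
  tau <- as.integer(round(P * 60 / fm_test$window_s))
  if (include_original) groups <- c(list(original = ".*"), groups)
  traces <- matrix(NA_real_, nrow(fm_test$values), length(groups),
                   dimnames = list(NULL, names(groups)))
  models <- vector("list", length(groups))
  names(models) <- names(groups)
  for (g in names(groups)) {
    pat <- paste(groups[[g]], collapse = "|")
    keep <- grepl(pat, fm_train$feature_names)
    if (!any(keep)) stop("feature group '", g, "' matches no features")
    sub_train <- fm_train
    sub_train$values <- fm_train$values[, keep, drop = FALSE]
    sub_train$feature_names <- fm_train$feature_names[keep]
    mdl <- train_patient_model(sub_train, model = model, seed = seed, ...)
    outp <- predict_windows(mdl, fm_test$values[, keep, drop = FALSE])
    traces[, g] <- firing_power(as.integer(outp), tau)
    models[[g]] <- mdl
  }
  list(fp = traces, models = models, tau = tau)
}

#' Standard ablation feature groups
#'
#' The band-power feature groups used for single-feature retraining:
#' each spectral band's relative power, the total band power and the
#' signal time variance (all channels of each).
#'
#' @return Named list of feature-name regular expressions.
#' @export
ablation_groups <- function() {
  list(delta = "/relpow_delta$",
       theta = "/relpow_theta$",
       band_8_13 = "/relpow_band_8_13$",
       band_13_30 = "/relpow_band_13_30$",
       gamma = "/relpow_gamma[1-4]$",
       total_power = "/total_power$",
       variance = "/variance$")
}

#' Firing Power versus feature scatter data
#'
#' Long-format table behind the Firing-Power scatter explanation: one
#' row per window with the Firing Power, the feature value and the
#' window label; optional `moments of interest` (user-supplied window
#' indices, e.g. false alarms under scrutiny) are flagged.
#'
#' @param fp Firing Power vector.
#' @param feature_values Feature value per window (same grid).
#' @param labels Window labels (same grid).
#' @param highlight_idx Optional integer indices of windows of interest.
#' @return Data frame with columns `fp`, `feature`, `label`,
#'   `highlight`.
#' @export
fp_feature_scatter <- function(fp, feature_values, labels = NULL,
                               highlight_idx = integer(0)) {
  n <- length(fp)
  if (length(feature_values) != n) stop("misaligned window grids")
  if (!is.null(labels) && length(labels) != n) {
    stop("misaligned window grids")
  }
  data.frame(fp = as.numeric(fp), feature = as.numeric(feature_values),
             label = if (is.null(labels)) NA_character_
                     else as.character(labels),
             highlight = seq_len(n) %in% highlight_idx)
}

#' Export an annotated Firing Power time plot as CSV
#'
#' Writes the data behind the standard time-series explanation: Firing
#' Power per window, the 0.7 threshold, alarm markers, refractory and
#' preictal/interictal state, and (when available) the sleep/awake
#' overlay — all on the common window grid. An optional rendered figure
#' is produced when `ggplot2` is installed and `plot_file` is given.
#'
#' @param window_start `POSIXct` window grid.
#' @param fp Firing Power vector.
#' @param alarm_idx Window indices of raised alarms.
#' @param labels Window labels (preictal/interictal, NA for ictal).
#' @param refractory Logical refractory mask (optional).
#' @param asleep Logical sleep state per window (optional; omitted from
#'   the file when absent).
#' @param path Output CSV path.
#' @param threshold Alarm threshold to record.
#' @param plot_file Optional path for a rendered figure (requires
#'   `ggplot2`).
#' @return The CSV path, invisibly.
#' @export
export_timeplot <- function(window_start, fp, alarm_idx, labels,
                            refractory = NULL, asleep = NULL, path,
                            threshold = 0.7, plot_file = NULL) {
  n <- length(fp)
  stopifnot(length(window_start) == n, length(labels) == n)
  df <- data.frame(window_start = format_iso8601(window_start),
                   fp = as.numeric(fp),
                   alarm = seq_len(n) %in% alarm_idx,
                   refractory = if (is.null(refractory)) FALSE
                                else as.logical(refractory),
                   label = as.character(labels))
  if (!is.null(asleep)) df$asleep <- as.logical(asleep)
  attr(df, "threshold") <- threshold
  write.csv(df, path, row.names = FALSE)
  if (!is.null(plot_file) &&
      requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(
      data.frame(t = window_start, fp = as.numeric(fp)),
      ggplot2::aes(x = t, y = fp)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                          colour = "red") +
      ggplot2::geom_vline(xintercept = window_start[alarm_idx],
                          colour = "orange", alpha = 0.7) +
      ggplot2::labs(x = NULL, y = "Firing Power") +
      ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
    ggplot2::ggsave(plot_file, gg, width = 9, height = 3)
  }
  invisible(path)
}
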