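# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# compact three-seizure patient used for parameter-recovery style checks
recovery_config <- function(seed, effect_size = 3, n_channels = 1,
                            min_separation_min = 90) {
  sim_config(n_seizures = 3, record_days = 0.185,
             n_channels = n_channels, true_preictal_min = 40,
             effect_size = effect_size,
             min_separation_min = min_separation_min,
             circadian_amplitude = 0, sleep_schedule = list(),
             seed = seed, allow_few = TRUE)
}

# minimal feature_matrix built directly (no signal synthesis) for
# training/evaluation plumbing tests
make_fm <- function(values, window_s = 5,
                    start_time = as.POSIXct("2024-03-01", tz = "UTC"),
                    labels = NULL) {
  nw <- nrow(values)
  colnames(values) <- colnames(values) %||%
    paste0("ch/", seq_len(ncol(values)))
  structure(list(
    values = values, feature_names = colnames(values),
    window_start = start_time + (seq_len(nw) - 1) * window_s,
    window_start_s = (seq_len(nw) - 1) * window_s,
    window_s = window_s, fs = 256, start_time = start_time,
    labels = labels %||% factor(rep(NA_character_, nw),
                                levels = c("interictal", "preictal")),
    excluded = rep(FALSE, nw),
    degenerate = matrix(FALSE, nw, 1),
    meta = list()), class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
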