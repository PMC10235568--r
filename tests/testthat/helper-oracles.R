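# Independent direct-formula oracles used to validate the package's
# vectorised implementations. They share only the definitions (same Hann
# taper convention for spectral features), never the code paths.

# direct-DFT Hann periodogram (O(n^2); independent of stats::fft);
# the DFT matrix is cached per window length
.dft_cache <- new.env(parent = emptyenv())

oracle_psd <- function(x, fs) {
  n <- length(x)
  key <- as.character(n)
  if (is.null(.dft_cache[[key]])) {
    nb <- n %/% 2 + 1
    k <- seq_len(nb) - 1
    t_idx <- seq_len(n) - 1
    .dft_cache[[key]] <- exp(-2i * pi * outer(k, t_idx) / n)
  }
  W <- .dft_cache[[key]]
  xd <- x - mean(x)
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  xw <- xd * h
  nb <- nrow(W)
  X <- as.vector(W %*% xw)
  scale <- c(1, rep(2, nb - 2), 1) / (fs * sum(h^2))
  list(psd = Mod(X)^2 * scale, f = (seq_len(nb) - 1) * fs / n, df = fs / n)
}

oracle_band_powers <- function(x, fs, bands = seizecast::eeg_bands()) {
  sp <- oracle_psd(x, fs)
  f_top <- min(128, fs / 2)
  total <- sum(sp$psd[sp$f >= 0.5 & sp$f <= f_top]) * sp$df
  sapply(seq_len(nrow(bands)), function(b) {
    mk <- sp$f >= bands$f_low[b] &
      (sp$f < bands$f_high[b] |
         (bands$f_high[b] >= fs / 2 & sp$f <= fs / 2))
    sum(sp$psd[mk]) * sp$df / total
  })
}

oracle_sef <- function(x, fs, fraction = 0.5) {
  sp <- oracle_psd(x, fs)
  f_top <- min(128, fs / 2)
  sel <- sp$f >= 0.5 & sp$f <= f_top
  cs <- cumsum(sp$psd[sel])
  i <- which(cs >= fraction * cs[length(cs)])[1]
  list(edge_hz = sp$f[sel][i], cum_power = cs[i] * sp$df)
}

oracle_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  d <- x - m
  m2 <- sum(d^2) / n
  c(mean = m, variance = sum(d^2) / (n - 1),
    skewness = (sum(d^3) / n) / m2^1.5,
    kurtosis = (sum(d^4) / n) / m2^2)
}

oracle_hjorth <- function(x) {
  d1 <- diff(x)
  d2 <- diff(d1)
  act <- var(x)
  mob <- sqrt(var(d1) / var(x))
  c(activity = act, mobility = mob,
    complexity = sqrt(var(d2) / var(d1)) / mob)
}

oracle_decorr <- function(x, fs) {
  n <- length(x)
  d <- x  # raw window: the saturation case requires no detrending
  r0 <- sum(d^2)
  for (k in seq_len(n - 1)) {
    rk <- sum(d[seq_len(n - k)] * d[seq.int(k + 1, n)])
    if (rk <= 0) return(k / fs)
  }
  n / fs
}

# brute-force Firing Power: literal re-summation at every index
oracle_firing_power <- function(o, tau) {
  vapply(seq_along(o), function(i) {
    mean(o[max(1, i - tau + 1):i])
  }, numeric(1))
}

# hand-rolled IRLS for weighted logistic regression
oracle_irls <- function(X, y, w = rep(1, length(y)), iters = 100,
                        tol = 1e-12) {
  Xd <- cbind(1, X)
  beta <- rep(0, ncol(Xd))
  for (it in seq_len(iters)) {
    eta <- as.vector(Xd %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- w * p * (1 - p)
    z <- eta + (y - p) / pmax(p * (1 - p), 1e-12)
    beta_new <- solve(crossprod(Xd, W * Xd), crossprod(Xd, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

# brute-force minimal flipping delta for feature j of a linear model
oracle_counterfactual_scan <- function(w, b, x, j, lim = 20,
                                       n_grid = 10000) {
  m0 <- sum(w * x) + b
  pred0 <- as.integer(m0 >= 0)
  deltas <- seq(-lim, lim, length.out = n_grid)
  flip <- vapply(deltas, function(d) {
    xx <- x
    xx[j] <- xx[j] + d
    as.integer(sum(w * xx) + b >= 0) != pred0
  }, logical(1))
  if (!any(flip)) return(NA_real_)
  deltas[flip][which.min(abs(deltas[flip]))]
}
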