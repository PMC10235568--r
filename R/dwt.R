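# Orthonormal Daubechies-4 (8-tap) filter pair, periodized convolution.
# Low-pass coefficients sum to sqrt(2); the high-pass filter is the
# quadrature mirror g[m] = (-1)^m h[L-1-m].
db4_lowpass <- function() {
  c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
    -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
    0.03288301166698295, -0.01059740178499728)
}

db4_highpass <- function() {
  h <- db4_lowpass()
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# One periodized analysis step on a matrix (coefficients in rows, one
# signal per column): returns approximation and detail halves.
dwt_step_periodized <- function(a, h, g) {
  n <- nrow(a)
  stopifnot(n %% 2 == 0)
  n2 <- n / 2L
  approx <- matrix(0, n2, ncol(a))
  detail <- matrix(0, n2, ncol(a))
  # circular alignment follows the common periodized-DWT convention
  # (filter centred so that coefficient k sits at sample 2k)
  base <- 2L * (seq_len(n2) - 1L) - 3L
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    approx <- approx + h[m] * a[idx, , drop = FALSE]
    detail <- detail + g[m] * a[idx, , drop = FALSE]
  }
  list(approx = approx, detail = detail)
}

#' Periodized Daubechies-4 discrete wavelet transform
#'
#' Computes an orthonormal multi-level DWT with the db4 (8-tap) filter
#' pair and periodic boundary handling, for one signal (vector) or many
#' signals at once (matrix with one signal per column). Periodization
#' keeps the transform orthogonal, so the summed squared coefficients
#' equal the signal energy exactly.
#'
#' @param x Numeric vector or matrix (signals in columns); the length
#'   must be divisible by `2^levels`.
#' @param levels Number of decomposition levels.
#' @return A list with `details` (list of coefficient matrices, level 1 =
#'   finest) and `approx` (final approximation coefficients).
#' @export
dwt_db4 <- function(x, levels = 8) {
  a <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(a) %% 2^levels != 0) {
    stop("signal length must be divisible by 2^levels")
  }
  h <- db4_lowpass(); g <- db4_highpass()
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- dwt_step_periodized(a, h, g)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(details = details, approx = a)
}

#' Wavelet detail-coefficient energies (D1-D8)
#'
#' Energy (sum of squared detail coefficients) per decomposition level of
#' an 8-level periodized db4 DWT. Level D1 is the finest scale
#' (fs/4-fs/2 band), D8 the coarsest.
#'
#' @param x Numeric vector or matrix (signals in columns); length at
#'   least `2^levels` and divisible by `2^levels`.
#' @param levels Number of levels (default 8).
#' @return For a vector input, a named numeric vector `E_D1`..`E_D8`;
#'   for a matrix, an `levels + 1` column matrix whose last column
#'   `E_A` is the approximation energy (one row per signal).
#' @export
wavelet_energies <- function(x, levels = 8) {
  vec <- !is.matrix(x)
  if (vec && length(x) < 2^levels) {
    stop("window shorter than 2^levels samples")
  }
  w <- dwt_db4(x, levels)
  E <- vapply(w$details, function(d) colSums(d^2),
              numeric(ncol(w$approx)))
  E <- matrix(E, ncol = levels)
  out <- cbind(E, colSums(w$approx^2))
  colnames(out) <- c(paste0("E_D", seq_len(levels)), "E_A")
  if (vec) out[1, seq_len(levels)] else out
}
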