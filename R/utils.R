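#' Derive a reproducible substream seed
#'
#' Deterministically maps a master seed and a stream index to a new integer
#' seed below 2^31, so that independent simulation stages (scheduling,
#' per-block noise, artifacts, ensemble members, surrogates) draw from
#' decoupled streams while the whole run stays reproducible from one seed.
#'
#' @param seed Integer master seed.
#' @param k Integer stream index (any non-negative integer).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k) * 104729 + 11
  as.integer(s %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sz <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Format / parse ISO-8601 UTC timestamps
#'
#' Helpers used by the annotation and record containers. Timestamps are
#' always interpreted in UTC.
#'
#' @param t A `POSIXct` vector (`format_iso8601`) or character vector
#'   (`parse_iso8601`).
#' @return A character vector, respectively a `POSIXct` vector in UTC.
#' @export
format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

#' @rdname format_iso8601
#' @export
parse_iso8601 <- function(t) {
  out <- as.POSIXct(t, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(out) && !anyNA(t)) {
    stop("timestamps must be ISO-8601 (YYYY-MM-DDTHH:MM:SS[.sss]Z)")
  }
  out
}

# total overlap (in the units of the inputs) between the interval [a0, a1)
# and a set of intervals given as two vectors of starts/ends
interval_overlap <- function(a0, a1, starts, ends) {
  if (length(starts) == 0) return(0)
  sum(pmax(0, pmin(a1, ends) - pmax(a0, starts)))
}

# does point x fall in any half-open interval [start, end)?
point_in_intervals <- function(x, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (i in seq_along(starts)) out <- out | (x >= starts[i] & x < ends[i])
  out
}
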