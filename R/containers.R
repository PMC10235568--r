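#' Continuous multichannel EEG recording
#'
#' A lightweight container for a continuous recording: a samples-by-
#' channels matrix of amplitudes (microvolt), the sampling rate, unique
#' channel labels and the absolute start time.
#'
#' @param signal Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling frequency in Hz.
#' @param channel_names Unique channel labels (one per column).
#' @param start_time Absolute start time (`POSIXct`).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, fs, channel_names, start_time) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(signal), fs > 0,
            length(channel_names) == ncol(signal),
            inherits(start_time, "POSIXct"))
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  colnames(signal) <- channel_names
  structure(list(signal = signal, fs = fs,
                 channel_names = channel_names,
                 start_time = start_time,
                 duration_s = nrow(signal) / fs),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %.1f s @ %g Hz, start %s\n",
              ncol(x$signal), x$duration_s, x$fs,
              format_iso8601(x$start_time)))
  invisible(x)
}

#' Seizure onset annotations
#'
#' Ordered absolute seizure onset (and optional offset) timestamps for one
#' patient. Onsets must be strictly increasing and offsets, when present,
#' must follow their onsets.
#'
#' @param onset `POSIXct` vector of onset times.
#' @param offset Optional `POSIXct` vector of offsets (same length).
#' @return An object of class `seizure_annotation`.
#' @export
seizure_annotation <- function(onset, offset = NULL) {
  onset <- as.POSIXct(onset, tz = "UTC")
  if (length(onset) > 1 && any(diff(as.numeric(onset)) <= 0)) {
    stop("seizure onsets must be strictly increasing and without duplicates")
  }
  if (!is.null(offset)) {
    offset <- as.POSIXct(offset, tz = "UTC")
    stopifnot(length(offset) == length(onset))
    if (any(as.numeric(offset) <= as.numeric(onset))) {
      stop("offsets must be later than their onsets")
    }
  }
  structure(list(onset = onset, offset = offset),
            class = "seizure_annotation")
}

#' @export
length.seizure_annotation <- function(x) length(x$onset)

#' @export
print.seizure_annotation <- function(x, ...) {
  cat(sprintf("<seizure_annotation> %d onset(s)\n", length(x$onset)))
  if (length(x$onset)) cat(paste0("  ", format_iso8601(x$onset)), sep = "\n")
  invisible(x)
}

#' Write / read seizure annotations as CSV
#'
#' The exchange format is a CSV with header `onset_iso8601` and an
#' optional second column `offset_iso8601`; timestamps are ISO-8601 UTC.
#' Reading an annotation file with a header but no rows yields an empty
#' annotation.
#'
#' @param ann A [seizure_annotation] object.
#' @param path File path.
#' @return `read_annotations` returns a [seizure_annotation].
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "seizure_annotation"))
  df <- data.frame(onset_iso8601 = format_iso8601(ann$onset))
  if (!is.null(ann$offset)) df$offset_iso8601 <- format_iso8601(ann$offset)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"onset_iso8601" %in% names(df)) {
    stop("annotation file must have an 'onset_iso8601' column")
  }
  if (nrow(df) == 0) {
    return(seizure_annotation(as.POSIXct(character(0), tz = "UTC")))
  }
  onset <- parse_iso8601(df$onset_iso8601)
  offset <- if ("offset_iso8601" %in% names(df)) {
    parse_iso8601(df$offset_iso8601)
  }
  seizure_annotation(onset, offset)
}

#' Validate annotations against a recording
#'
#' Checks that every onset lies inside the record's time span.
#'
#' @param ann A [seizure_annotation].
#' @param record An [eeg_record].
#' @return The annotation, invisibly; errors if any onset falls outside
#'   the recording.
#' @export
validate_annotations <- function(ann, record) {
  stopifnot(inherits(ann, "seizure_annotation"),
            inherits(record, "eeg_record"))
  t0 <- as.numeric(record$start_time)
  rel <- as.numeric(ann$onset) - t0
  if (any(rel < 0)) stop("seizure onset before record start")
  if (any(rel > record$duration_s)) stop("seizure onset after record end")
  invisible(ann)
}

#' Write / read an EEG recording container
#'
#' Default on-disk container: one little-endian float32 array file
#' (`<path>.f32`, channel-major sample order) plus a JSON sidecar
#' (`<path>.json`) holding the sampling rate, channel names, start time
#' and duration.
#'
#' @param record An [eeg_record].
#' @param path Path prefix (without extension).
#' @return `read_record` returns an [eeg_record]. Note the float32
#'   round-trip quantizes amplitudes to single precision.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  con <- file(paste0(path, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(record$signal), con, size = 4, endian = "little")
  meta <- list(fs = record$fs, channel_names = record$channel_names,
               start_time = format_iso8601(record$start_time),
               n_samples = nrow(record$signal))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".f32"), "rb")
  on.exit(close(con))
  n <- meta$n_samples * length(meta$channel_names)
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  eeg_record(matrix(x, nrow = meta$n_samples), fs = meta$fs,
             channel_names = meta$channel_names,
             start_time = parse_iso8601(meta$start_time))
}
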