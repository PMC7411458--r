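#' Single-lead ECG signal
#'
#' The canonical container every processing stage consumes and returns: a
#' uniformly sampled amplitude series in millivolts plus its sampling rate.
#' All sample indices reported anywhere in the package (detections, beat
#' annotations, ground truth) are 0-based, matching WFDB convention.
#'
#' @param samples numeric vector of amplitudes (mV). Must be finite.
#' @param fs sampling rate in Hz, > 0.
#' @param start_index 0-based offset of the first sample in the source record.
#' @param lead_name optional lead label (e.g. "MLII", "V1").
#' @return An object of class `ecg_signal`: a list with fields `samples`,
#'   `fs`, `start_index`, `lead_name`.
#' @examples
#' x <- ecg_signal(sin(2 * pi * 1 * seq(0, 1, by = 1/250)), fs = 250)
#' x
#' @export
ecg_signal <- function(samples, fs, start_index = 0L, lead_name = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (length(samples) && !all(is.finite(samples)))
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (start_index < 0) stop("`start_index` must be >= 0", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs),
         start_index = as.integer(start_index),
         lead_name = lead_name),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.2f s)%s\n",
              n, x$fs, n / x$fs,
              if (is.null(x$lead_name)) "" else paste0(", lead ", x$lead_name)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Reference beat annotations
#'
#' Strictly increasing 0-based sample indices of annotated R-peaks, with
#' optional per-beat annotation symbols. Input order does not matter; the
#' constructor sorts (keeping labels aligned) and rejects duplicates.
#'
#' @param r_indices integer-ish vector of 0-based R-peak sample indices.
#' @param labels optional character vector of per-beat symbols, same length.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(r_indices, labels = NULL) {
  r_indices <- as.integer(round(as.numeric(r_indices)))
  if (length(r_indices) && any(r_indices < 0))
    stop("beat indices must be >= 0", call. = FALSE)
  if (!is.null(labels) && length(labels) != length(r_indices))
    stop("`labels` must match `r_indices` in length", call. = FALSE)
  ord <- order(r_indices)
  r_indices <- r_indices[ord]
  if (!is.null(labels)) labels <- labels[ord]
  if (anyDuplicated(r_indices))
    stop("beat indices must be strictly increasing (duplicates found)",
         call. = FALSE)
  structure(list(r_indices = r_indices, labels = labels),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d beats\n", length(x$r_indices)))
  invisible(x)
}

#' @export
length.beat_annotations <- function(x) length(x$r_indices)

# Coerce a beat index argument (vector or beat_annotations) to integer vector.
beat_indices <- function(x) {
  if (inherits(x, "beat_annotations")) x$r_indices
  else as.integer(round(as.numeric(x)))
}
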