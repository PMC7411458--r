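# Baseline-wander removal by sliding-window median subtraction.
#
# The estimated baseline at sample k is the median of the window centred on
# k; W = fs * window_time + 1, forced odd, and must span at least 0.6 s so
# the window always contains more isoelectric samples than QRS samples. In
# streaming mode the corrected sample is emitted with a fixed (W-1)/2-sample
# latency; the timeline itself is not shifted.

#' Baseline correction configuration
#'
#' @param window_time median window length in seconds (default 0.7). The
#'   derived sample window `W = fs * window_time + 1` is rounded up to odd
#'   and must cover at least 0.6 s.
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(window_time = 0.7) {
  if (!is.numeric(window_time) || window_time < 0.6)
    stop("`window_time` must be at least 0.6 s", call. = FALSE)
  structure(list(window_time = window_time), class = "baseline_config")
}

#' Median window length in samples
#'
#' @param fs sampling rate, Hz.
#' @param config a [baseline_config].
#' @return Odd integer window length `W >= 3`.
#' @export
baseline_window_length <- function(fs, config = baseline_config()) {
  w <- as.integer(ceiling(fs * config$window_time + 1))
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 3L)
}

# Median of each full window plus truncated windows at both edges.
# Returns the baseline estimate, same length as x.
rolling_median_full <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  med <- stats::runmed(x, w, endrule = "keep")
  for (k in seq_len(min(half, n)))
    med[k] <- stats::median(x[1:min(n, k + half)])
  if (n > half)
    for (k in (n - half + 1L):n)
      med[k] <- stats::median(x[max(1L, k - half):n])
  med
}

#' Subtract the sliding-window median baseline
#'
#' For interior samples the output is
#' \eqn{Y_k = X_k - \mathrm{median}(X_{k-(W-1)/2}, \ldots, X_{k+(W-1)/2})}.
#' The first and last (W-1)/2 samples use the median over the truncated
#' available window, keeping output length equal to input length.
#'
#' @param signal an [ecg_signal].
#' @param config a [baseline_config].
#' @return The corrected [ecg_signal].
#' @export
baseline_correct <- function(signal, config = baseline_config()) {
  stopifnot(inherits(signal, "ecg_signal"))
  w <- baseline_window_length(signal$fs, config)
  x <- signal$samples
  if (length(x) < w)
    stop("signal (", length(x), " samples) is shorter than the median ",
         "window (", w, " samples)", call. = FALSE)
  y <- x - rolling_median_full(x, w)
  ecg_signal(y, fs = signal$fs, start_index = signal$start_index,
             lead_name = signal$lead_name)
}
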