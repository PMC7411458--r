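# Causal preprocessing: 50 Hz notch + order-40 equiripple FIR low-pass.
#
# Both filters are run strictly causally (zero-padded history, no zero-phase
# filtering) so that chunk-wise streaming output is sample-for-sample equal
# to whole-signal output. Group delay is therefore not compensated here; the
# pipeline level subtracts the FIR delay (order/2 samples) when mapping
# detections back to the raw timeline.

#' Preprocessing filter configuration
#'
#' @param notch_freq powerline frequency to remove, Hz (50 by default; set
#'   60 for 60 Hz regions).
#' @param notch_q quality factor of the IIR notch (bandwidth = freq/Q).
#' @param fir_order FIR low-pass order N (N + 1 taps).
#' @param fir_passband passband edge in Hz; `NULL` scales the reference
#'   design (40 Hz at fs = 500) proportionally in normalized frequency.
#' @param fir_stopband stopband edge in Hz; `NULL` scales the reference
#'   design (100 Hz at fs = 500, i.e. "noise greater than 100 Hz" removed).
#' @param fir_coefficients optional explicit taps; set by [design_fir()].
#' @param compensate_delay subtract the FIR group delay (order/2 samples)
#'   from reported indices at the pipeline level.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(notch_freq = 50, notch_q = 30, fir_order = 40,
                          fir_passband = NULL, fir_stopband = NULL,
                          fir_coefficients = NULL, compensate_delay = FALSE) {
  if (notch_freq <= 0) stop("`notch_freq` must be > 0", call. = FALSE)
  if (notch_q <= 0) stop("`notch_q` must be > 0", call. = FALSE)
  if (fir_order < 1) stop("`fir_order` must be >= 1", call. = FALSE)
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 fir_order = as.integer(fir_order),
                 fir_passband = fir_passband, fir_stopband = fir_stopband,
                 fir_coefficients = fir_coefficients,
                 compensate_delay = isTRUE(compensate_delay)),
            class = "filter_config")
}

# --- streaming causal filter primitives --------------------------------------

# FIR: y[n] = sum_i b[i+1] * x[n-i], zero history at stream start.
new_fir_state <- function(b) list(b = as.numeric(b),
                                  tail = numeric(length(b) - 1L))

fir_step <- function(state, x) {
  nb <- length(state$b)
  xx <- c(state$tail, as.numeric(x))
  if (nb == 1L) {
    y <- state$b * as.numeric(x)
  } else {
    y <- as.numeric(stats::filter(xx, state$b, method = "convolution",
                                  sides = 1L))
    y <- y[(nb):length(xx)]
    # stats::filter needs nb-1 history samples; tail provides exactly that,
    # but when it is shorter than nb-1 nothing is lost because we pre-pad.
  }
  tail_len <- nb - 1L
  new_tail <- if (tail_len > 0L) xx[(length(xx) - tail_len + 1L):length(xx)]
              else numeric(0)
  list(state = list(b = state$b, tail = new_tail), y = y)
}

# Biquad IIR (direct form I split into FIR part + order-2 recursion).
new_iir2_state <- function(b, a) list(b = as.numeric(b), a = as.numeric(a),
                                      xtail = numeric(2), ytail = numeric(2))

iir2_step <- function(state, x) {
  xx <- c(state$xtail, as.numeric(x))
  v <- as.numeric(stats::filter(xx, state$b, method = "convolution",
                                sides = 1L))[3:length(xx)]
  y <- as.numeric(stats::filter(v, -state$a[2:3], method = "recursive",
                                init = state$ytail))
  n <- length(y)
  list(state = list(b = state$b, a = state$a,
                    xtail = xx[(length(xx) - 1L):length(xx)],
                    ytail = c(y[n], if (n >= 2L) y[n - 1L] else state$ytail[1L])),
       y = y)
}

# --- filter design -----------------------------------------------------------

# RBJ-cookbook biquad notch; returns list(b, a) normalized to a0 = 1.
design_notch <- function(fs, notch_freq = 50, notch_q = 30) {
  if (notch_freq >= fs / 2)
    stop("notch frequency (", notch_freq, " Hz) must be below Nyquist (",
         fs / 2, " Hz)", call. = FALSE)
  w0 <- 2 * pi * notch_freq / fs
  alpha <- sin(w0) / (2 * notch_q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

#' Design the FIR low-pass
#'
#' Equiripple (Parks-McClellan) low-pass of the configured order. The
#' reference design at fs = 500 Hz uses a 40 Hz passband edge and a 100 Hz
#' stopband edge (the QRS band is preserved; EMG content above 100 Hz is
#' rejected); for other sampling rates the edges scale proportionally in
#' normalized frequency unless given explicitly.
#'
#' @param fs sampling rate, Hz.
#' @param config a [filter_config].
#' @return The config with `fir_coefficients` filled (order + 1 taps,
#'   DC gain within 1% of unity).
#' @export
design_fir <- function(fs, config = filter_config()) {
  fpass <- if (is.null(config$fir_passband)) 0.16 * (fs / 2)
           else config$fir_passband
  fstop <- if (is.null(config$fir_stopband)) 0.40 * (fs / 2)
           else config$fir_stopband
  if (fstop >= fs / 2)
    stop("FIR stopband edge (", fstop, " Hz) must be below Nyquist (",
         fs / 2, " Hz)", call. = FALSE)
  if (fpass <= 0 || fpass >= fstop)
    stop("need 0 < passband (", fpass, ") < stopband (", fstop, ")",
         call. = FALSE)
  b <- tryCatch(
    signal::remez(config$fir_order,
                  c(0, fpass, fstop, fs / 2) / (fs / 2),
                  c(1, 1, 0, 0)),
    error = function(e) stop("FIR design failed for order ",
                             config$fir_order, ", edges ", fpass, "/", fstop,
                             " Hz at fs ", fs, ": ", conditionMessage(e),
                             call. = FALSE))
  config$fir_passband <- fpass
  config$fir_stopband <- fstop
  config$fir_coefficients <- as.numeric(b)
  config
}

# --- public filtering operations ---------------------------------------------

#' Notch-filter powerline interference
#'
#' Second-order IIR notch at `config$notch_freq` (50 Hz default), run
#' causally. DC gain is unity; a steady sinusoid at the notch frequency is
#' suppressed far below 1% of its input amplitude.
#'
#' @param signal an [ecg_signal].
#' @param config a [filter_config].
#' @return The filtered [ecg_signal] (same length and fs).
#' @export
notch_filter <- function(signal, config = filter_config()) {
  stopifnot(inherits(signal, "ecg_signal"))
  d <- design_notch(signal$fs, config$notch_freq, config$notch_q)
  st <- new_iir2_state(d$b, d$a)
  y <- iir2_step(st, signal$samples)$y
  ecg_signal(y, fs = signal$fs, start_index = signal$start_index,
             lead_name = signal$lead_name)
}

#' FIR low-pass filter
#'
#' Causal finite impulse response filter
#' \eqn{y_n = \sum_{i=0}^{N} a_i x_{n-i}} with zero-padded history, so the
#' output has the same length as the input. Uses `config$fir_coefficients`
#' if present, otherwise designs them for the signal's rate via
#' [design_fir()].
#'
#' @param signal an [ecg_signal].
#' @param config a [filter_config].
#' @return The filtered [ecg_signal].
#' @export
fir_lowpass <- function(signal, config = filter_config()) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (is.null(config$fir_coefficients))
    config <- design_fir(signal$fs, config)
  st <- new_fir_state(config$fir_coefficients)
  y <- fir_step(st, signal$samples)$y
  ecg_signal(y, fs = signal$fs, start_index = signal$start_index,
             lead_name = signal$lead_name)
}
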