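# Independent brute-force oracles used to pin down the hand-verifiable
# kernels. These deliberately share no code with the implementation.

# Direct double-loop evaluation of the causal FIR difference equation
# y[n] = sum_i b[i] x[n-i] with zero-padded history.
bf_fir <- function(b, x) {
  y <- numeric(length(x))
  for (n in seq_along(x)) {
    acc <- 0
    for (i in seq_along(b)) {
      k <- n - i + 1L
      if (k >= 1L) acc <- acc + b[[i]] * x[[k]]
    }
    y[[n]] <- acc
  }
  y
}

# Sort-and-pick median baseline subtraction with truncated edge windows.
bf_baseline <- function(x, w) {
  half <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(k) {
    win <- sort(x[max(1L, k - half):min(n, k + half)])
    m <- length(win)
    med <- if (m %% 2L == 1L) win[[(m + 1L) %/% 2L]]
           else (win[[m %/% 2L]] + win[[m %/% 2L + 1L]]) / 2
    x[[k]] - med
  }, numeric(1))
}

# Loop evaluation of the signed-square window difference.
bf_window_difference <- function(x) {
  n <- length(x)
  y <- numeric(n - 2L)
  for (i in seq_len(n - 2L)) {
    d <- x[[i + 2L]] - x[[i]]
    y[[i]] <- if (d > 0) d^2 else if (d < 0) -d^2 else 0
  }
  y
}

# Exhaustive maximum bipartite matching (max TP) between reference beats
# and detections under a tolerance window; feasible for <= 10 beats.
bf_match_optimal <- function(ref, det, tol) {
  if (!length(ref)) return(0L)
  best <- bf_match_optimal(ref[-1L], det, tol)
  for (j in which(abs(det - ref[[1L]]) <= tol))
    best <- max(best, 1L + bf_match_optimal(ref[-1L], det[-j], tol))
  best
}

# Single-sided spectral amplitude at frequency f (whole-vector DFT bin).
amp_at <- function(x, fs, f) {
  n <- length(x)
  2 * Mod(stats::fft(x))[[round(f * n / fs) + 1L]] / n
}

# Short ground-truthed clean record used by several detector tests.
clean_record <- function(duration = 20, seed = 2, fs = 500, ...) {
  synth_ecg(synth_config(fs = fs, duration = duration, seed = seed, ...))
}
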