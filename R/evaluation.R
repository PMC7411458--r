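# Tolerance-matched beat-detection scoring: TP/FN/FP counts and the derived
# sensitivity Se = TP/(TP+FN) and positive predictivity +P = TP/(TP+FP),
# both in percent.

#' Round half-up to a number of decimals
#'
#' Report-style rounding (99.695 -> 99.70), unlike R's banker's rounding.
#' @param x numeric vector.
#' @param digits decimal places (default 2, matching report tables).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Match detections against reference beats
#'
#' One-to-one greedy matching in chronological order: each reference beat
#' takes the nearest unmatched detection within `tolerance` (ties: the
#' earlier detection). Unmatched references count as FN, unmatched
#' detections as FP.
#'
#' @param detections strictly increasing 0-based detection indices (vector
#'   or [beat_annotations]).
#' @param reference strictly increasing 0-based reference indices (vector
#'   or [beat_annotations]).
#' @param tolerance matching tolerance in seconds (default 0.15 s, standard
#'   beat-matching practice).
#' @param fs sampling rate in Hz.
#' @return An `eval_result` list: counts `tp`, `fn`, `fp`, metrics `se`,
#'   `ppv` (percent), and `matched` (data.frame of matched index pairs).
#' @export
match_beats <- function(detections, reference, tolerance = 0.15, fs) {
  det <- beat_indices(detections)
  ref <- beat_indices(reference)
  if (is.unsorted(det, strictly = TRUE))
    stop("`detections` must be strictly increasing", call. = FALSE)
  if (is.unsorted(ref, strictly = TRUE))
    stop("`reference` must be strictly increasing", call. = FALSE)
  tol <- tolerance * fs
  used <- logical(length(det))
  m_ref <- integer(0)
  m_det <- integer(0)
  j_lo <- 1L
  for (i in seq_along(ref)) {
    while (j_lo <= length(det) &&
           (used[j_lo] || det[j_lo] < ref[i] - tol)) j_lo <- j_lo + 1L
    best <- 0L
    best_d <- Inf
    j <- j_lo
    while (j <= length(det) && det[j] <= ref[i] + tol) {
      if (!used[j]) {
        d <- abs(det[j] - ref[i])
        if (d < best_d) { best_d <- d; best <- j }
      }
      j <- j + 1L
    }
    if (best > 0L) {
      used[best] <- TRUE
      m_ref <- c(m_ref, ref[i])
      m_det <- c(m_det, det[best])
    }
  }
  tp <- length(m_ref)
  fn <- length(ref) - tp
  fp <- length(det) - tp
  met <- compute_metrics(tp, fn, fp)
  structure(list(tp = tp, fn = fn, fp = fp,
                 n_reference = length(ref), n_detections = length(det),
                 se = met$se, ppv = met$ppv,
                 matched = data.frame(reference = m_ref, detection = m_det)),
            class = "eval_result")
}

#' Sensitivity and positive predictivity from counts
#'
#' `Se = 100 * TP / (TP + FN)`; `+P = 100 * TP / (TP + FP)`.
#'
#' @param tp,fn,fp non-negative counts.
#' @return list with `se` and `ppv` in percent (unrounded). A zero
#'   denominator yields `NA` with a warning — the metric is undefined, not
#'   0 or 100.
#' @export
compute_metrics <- function(tp, fn, fp) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0)
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("Se undefined: no reference beats (TP + FN = 0)", call. = FALSE)
    NA_real_
  }
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
    warning("+P undefined: no detections (TP + FP = 0)", call. = FALSE)
    NA_real_
  }
  list(se = se, ppv = ppv)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> TP=%d FN=%d FP=%d  Se=%.2f%%  +P=%.2f%%\n",
              x$tp, x$fn, x$fp, round_half_up(x$se), round_half_up(x$ppv)))
  invisible(x)
}

#' Evaluate the detector on one record
#'
#' Runs the full detection pipeline on a record and scores it against
#' reference annotations. Reference beats (and detections) inside the
#' detector's warm-up span are excluded from scoring, since the detector by
#' design does not report beats there.
#'
#' @param record an [ecg_signal], or a WFDB record path (without
#'   extension), or a CSV path (then supply `fs`).
#' @param annotations a [beat_annotations], index vector, or path to a WFDB
#'   annotation file.
#' @param config a [pipeline_config] (filters, baseline, detector,
#'   thresholds).
#' @param tolerance matching tolerance in seconds.
#' @param channel WFDB channel if `record` is a path.
#' @param fs sampling rate if `record` is a CSV path.
#' @return An `eval_result` (as [match_beats()]), with the detection events
#'   attached as `$events`.
#' @export
evaluate_record <- function(record, annotations,
                            config = pipeline_config(),
                            tolerance = 0.15, channel = 0L, fs = NULL) {
  if (is.character(record)) {
    record <- if (grepl("\\.(csv|tsv|txt)$", record)) {
      if (is.null(fs)) stop("`fs` is required for CSV input", call. = FALSE)
      read_ecg_csv(record, fs = fs)
    } else read_wfdb(record, channel = channel)
  }
  stopifnot(inherits(record, "ecg_signal"))
  if (is.character(annotations)) {
    annotations <- if (grepl("\\.(csv|tsv|txt)$", annotations)) {
      # plain text: one 0-based sample index per line (simulate --truth)
      beat_annotations(scan(annotations, what = numeric(), quiet = TRUE))
    } else read_annotations(annotations)
  }
  ref <- beat_indices(annotations)
  out <- run_pipeline(record, config)
  scope <- round(config$detector$warmup * record$fs)
  res <- match_beats(out$events$r_index[out$events$r_index >= scope],
                     ref[ref >= scope],
                     tolerance = tolerance, fs = record$fs)
  res$events <- out$events
  res
}

#' Pool evaluation results across records
#'
#' Sums TP/FN/FP over records before computing Se and +P (pooled metrics,
#' not the mean of per-record metrics), and tabulates per-record rows.
#'
#' @param results list of `eval_result` objects, optionally named by record.
#' @return An `eval_result` with a `per_record` data.frame attached.
#' @export
pool_results <- function(results) {
  stopifnot(length(results) > 0,
            all(vapply(results, inherits, logical(1), "eval_result")))
  tp <- sum(vapply(results, `[[`, numeric(1), "tp"))
  fn <- sum(vapply(results, `[[`, numeric(1), "fn"))
  fp <- sum(vapply(results, `[[`, numeric(1), "fp"))
  met <- compute_metrics(tp, fn, fp)
  per <- data.frame(
    record = if (is.null(names(results))) seq_along(results)
             else names(results),
    n_beats = vapply(results, `[[`, numeric(1), "n_reference"),
    tp = vapply(results, `[[`, numeric(1), "tp"),
    fn = vapply(results, `[[`, numeric(1), "fn"),
    fp = vapply(results, `[[`, numeric(1), "fp"),
    se = round_half_up(vapply(results, `[[`, numeric(1), "se")),
    ppv = round_half_up(vapply(results, `[[`, numeric(1), "ppv"))
  )
  structure(list(tp = tp, fn = fn, fp = fp,
                 n_reference = tp + fn, n_detections = tp + fp,
                 se = met$se, ppv = met$ppv, per_record = per),
            class = "eval_result")
}
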