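# Adaptive Max-Min Threshold (MMT) R-wave detector.
#
# Pipeline: signed-square window difference -> threshold initialization over
# a post-warm-up span -> paired S1/S2 slope-extremum detection -> RR-interval
# error correction (missed-beat redetection at reduced thresholds, too-close
# rejection) -> adaptive threshold update with an amplitude-trend freeze.
#
# One streaming engine implements both the whole-signal and the chunked API,
# so batch and streaming outputs are identical by construction. All indices
# in returned events are 0-based on the processed-signal timeline.

#' Detector thresholds and coefficients
#'
#' Holds the live threshold triple and the dimensionless coefficients that
#' govern initialization and adaptation:
#' \itemize{
#'   \item `t_r` amplitude threshold on the corrected ECG (mV);
#'   \item `t_max`, `t_min` thresholds on the signed-square difference;
#'   \item `coef1`, `coef2` initialization gains
#'     (`t_r = coef1 * max(X)`, `t_max/t_min = coef2 * extrema(Y)`);
#'   \item `coef`, `rate` adaptation gain and memory:
#'     `T <- T * rate + measurement * coef * (1 - rate)`.
#' }
#'
#' @param t_r,t_max,t_min live threshold values (usually filled by
#'   [init_thresholds()]).
#' @param coef1,coef2,coef positive gains (defaults 0.5, 0.4, 0.5).
#' @param rate memory in `[0, 1]` (default 0.8).
#' @return A list of class `mmt_thresholds`.
#' @export
mmt_thresholds <- function(t_r = NA_real_, t_max = NA_real_,
                           t_min = NA_real_, coef1 = 0.5, coef2 = 0.4,
                           coef = 0.5, rate = 0.8) {
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]", call. = FALSE)
  if (coef1 <= 0 || coef2 <= 0 || coef <= 0)
    stop("`coef1`, `coef2`, `coef` must be > 0", call. = FALSE)
  structure(list(t_r = t_r, t_max = t_max, t_min = t_min,
                 coef1 = coef1, coef2 = coef2, coef = coef, rate = rate),
            class = "mmt_thresholds")
}

#' Detector configuration
#'
#' @param refractory_window maximum S1-to-S2 span in seconds (default 0.2 s,
#'   the physiological upper bound on QRS slope-pair spacing).
#' @param warmup seconds of signal excluded at the start (filter
#'   transients), default 1.
#' @param init_span seconds after warm-up used for threshold
#'   initialization, default 2.
#' @param missed_factor RR ratio above which a missed beat is suspected
#'   (default 1.66).
#' @param false_factor RR ratio below which a detection is rejected as a
#'   misjudgment (default 0.6).
#' @param redetect_scale threshold reduction per redetection pass
#'   (default 0.90).
#' @param max_redetect maximum successive reductions per gap (default 3).
#' @param trend_freeze_count consecutive same-direction amplitude changes
#'   that freeze threshold adaptation (default 2).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(refractory_window = 0.2, warmup = 1.0,
                            init_span = 2.0, missed_factor = 1.66,
                            false_factor = 0.6, redetect_scale = 0.90,
                            max_redetect = 3L, trend_freeze_count = 2L) {
  if (redetect_scale <= 0 || redetect_scale >= 1)
    stop("`redetect_scale` must be in (0, 1)", call. = FALSE)
  if (!(missed_factor > 1 && 1 > false_factor && false_factor > 0))
    stop("need missed_factor > 1 > false_factor > 0", call. = FALSE)
  if (refractory_window <= 0 || warmup < 0 || init_span <= 0)
    stop("invalid timing parameters", call. = FALSE)
  structure(list(refractory_window = refractory_window, warmup = warmup,
                 init_span = init_span, missed_factor = missed_factor,
                 false_factor = false_factor, redetect_scale = redetect_scale,
                 max_redetect = as.integer(max_redetect),
                 trend_freeze_count = as.integer(trend_freeze_count)),
            class = "detector_config")
}

#' Streaming detector state
#'
#' @param last_r_index 0-based index of the last accepted R peak, or `NULL`.
#' @param last_dif previous accepted RR interval in samples, or `NULL`.
#' @param prev_amp amplitude of the previous accepted R peak (mV), or `NULL`.
#' @param trend_direction +1 / -1 / 0 for the current amplitude trend.
#' @param trend_count consecutive same-direction amplitude changes.
#' @return A list of class `detector_state`.
#' @export
detector_state <- function(last_r_index = NULL, last_dif = NULL,
                           prev_amp = NULL, trend_direction = 0L,
                           trend_count = 0L) {
  structure(list(last_r_index = last_r_index, last_dif = last_dif,
                 prev_amp = prev_amp,
                 trend_direction = as.integer(trend_direction),
                 trend_count = as.integer(trend_count)),
            class = "detector_state")
}

# --- window difference -------------------------------------------------------

#' Signed-square window difference
#'
#' `Y[n] = sign(X[n+2] - X[n]) * (X[n+2] - X[n])^2` (0-based), so `Y` keeps
#' the slope direction while quadratically emphasizing the steep QRS edges.
#' `Y` has length `length(X) - 2` and `Y[n]` is aligned with `X[n]`.
#'
#' @param signal an [ecg_signal] with at least 3 samples.
#' @return A list of class `diff_signal` with fields `values` and `fs`.
#' @export
window_difference <- function(signal) {
  stopifnot(inherits(signal, "ecg_signal"))
  x <- signal$samples
  if (length(x) < 3L)
    stop("signal must have at least 3 samples", call. = FALSE)
  d <- x[3:length(x)] - x[1:(length(x) - 2L)]
  structure(list(values = sign(d) * d^2, fs = signal$fs),
            class = "diff_signal")
}

#' @export
print.diff_signal <- function(x, ...) {
  cat(sprintf("<diff_signal> %d values @ %g Hz\n", length(x$values), x$fs))
  invisible(x)
}

# --- threshold initialization ------------------------------------------------

# Shared by init_thresholds() and the engine. x, yv are plain vectors on the
# processed timeline (1-based internally).
.init_th <- function(x, yv, fs, config, coefs) {
  w0 <- as.integer(round(config$warmup * fs))
  span <- as.integer(round(config$init_span * fs))
  if (length(x) < w0 + span)
    stop("signal too short for threshold initialization: needs ",
         config$warmup + config$init_span, " s (warm-up + init span)",
         call. = FALSE)
  xr <- (w0 + 1L):(w0 + span)
  yr <- (w0 + 1L):min(w0 + span, length(yv))
  coefs$t_r <- max(x[xr]) * coefs$coef1
  coefs$t_max <- max(yv[yr]) * coefs$coef2
  coefs$t_min <- min(yv[yr]) * coefs$coef2
  coefs
}

#' Initialize detection thresholds
#'
#' Computes `t_r = coef1 * max(X)`, `t_max = coef2 * max(Y)` and
#' `t_min = coef2 * min(Y)` over the initialization span
#' `[warmup, warmup + init_span)`. The first `warmup` seconds are excluded
#' because the causal notch/FIR filters are still settling there.
#'
#' @param signal the preprocessed, baseline-corrected [ecg_signal].
#' @param diff the matching [window_difference()] output.
#' @param config a [detector_config].
#' @param coefs an [mmt_thresholds] carrying the coefficients.
#' @return The [mmt_thresholds] with `t_r`, `t_max`, `t_min` filled.
#' @export
init_thresholds <- function(signal, diff, config = detector_config(),
                            coefs = mmt_thresholds()) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(diff, "diff_signal"))
  .init_th(signal$samples, diff$values, signal$fs, config, coefs)
}

# --- run scanning core -------------------------------------------------------

# Scan yv[from..to] (1-based) for S1/S2 pairs under fixed thresholds.
# A supra-threshold run of Y > t_max yields S1 = index of the run maximum;
# the next sub-threshold run of Y < t_min yields S2 = index of the run
# minimum. A pair within `refr` samples whose X window maximum exceeds t_r
# is a candidate; r = argmax X over [S1, S2] (ties: earliest).
#
# `complete` marks end-of-data: runs touching `to` are then final. Otherwise
# a run touching `to` (and any unpaired supra-threshold run before it) is
# left for the next call; `resume` is the earliest index that must be
# rescanned. Returns list(events, resume) with 1-based indices.
scan_core <- function(x, yv, t_max, t_min, t_r, refr, from, to,
                      complete, first_only = TRUE) {
  events <- list()
  if (from > to) return(list(events = events, resume = from))
  seg <- yv[from:to]
  sv <- integer(length(seg))
  sv[seg > t_max] <- 1L
  sv[seg < t_min] <- -1L
  r <- rle(sv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pending_idx <- NA_integer_
  pending_start <- NA_integer_
  for (j in seq_along(r$values)) {
    v <- r$values[[j]]
    if (v == 0L) next
    run_s <- from + starts[[j]] - 1L
    run_e <- from + ends[[j]] - 1L
    if (run_e >= to && !complete) {
      resume <- if (!is.na(pending_start)) min(pending_start, run_s) else run_s
      return(list(events = events, resume = resume))
    }
    if (v == 1L) {
      pending_idx <- run_s + which.max(yv[run_s:run_e]) - 1L
      pending_start <- run_s
    } else if (!is.na(pending_idx)) {
      s2 <- run_s + which.min(yv[run_s:run_e]) - 1L
      s1 <- pending_idx
      d1 <- yv[[s1]]
      d2 <- yv[[s2]]
      pending_idx <- NA_integer_
      pending_start <- NA_integer_
      if ((s2 - s1) <= refr) {
        rel <- which.max(x[s1:s2])
        amp <- x[[s1 + rel - 1L]]
        if (amp > t_r) {
          events[[length(events) + 1L]] <-
            list(s1 = s1, s2 = s2, r = s1 + rel - 1L,
                 amp = amp, d1 = d1, d2 = d2)
          if (first_only)
            return(list(events = events, resume = run_e + 1L))
        }
      }
    }
  }
  resume <- if (!is.na(pending_start)) pending_start else to + 1L
  list(events = events, resume = resume)
}

events_to_frame <- function(evs) {
  if (!length(evs))
    return(data.frame(s1 = integer(0), s2 = integer(0), r_index = integer(0),
                      r_amplitude = numeric(0), d_s1 = numeric(0),
                      d_s2 = numeric(0)))
  data.frame(
    s1 = vapply(evs, function(e) e$s1 - 1L, integer(1)),
    s2 = vapply(evs, function(e) e$s2 - 1L, integer(1)),
    r_index = vapply(evs, function(e) e$r - 1L, integer(1)),
    r_amplitude = vapply(evs, function(e) e$amp, numeric(1)),
    d_s1 = vapply(evs, function(e) e$d1, numeric(1)),
    d_s2 = vapply(evs, function(e) e$d2, numeric(1))
  )
}

#' Fixed-threshold MMT scan
#'
#' Scans the whole difference signal for S1/S2 slope pairs under fixed
#' (non-adaptive) thresholds and returns every candidate detection. This is
#' the primitive the adaptive detector applies segment-wise; it is also used
#' directly for missed-beat redetection at reduced thresholds.
#'
#' @param signal the baseline-corrected [ecg_signal] (`X`).
#' @param diff the matching [window_difference()] output (`Y`).
#' @param thresholds an [mmt_thresholds] with live values set.
#' @param config a [detector_config] (only `refractory_window` is used).
#' @param state optional [detector_state]; accepted for interface symmetry.
#' @return A data.frame of candidate events with 0-based columns `s1`,
#'   `s2`, `r_index` and values `r_amplitude`, `d_s1`, `d_s2`.
#' @export
scan_mmt <- function(signal, diff, thresholds, config = detector_config(),
                     state = NULL) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(diff, "diff_signal"))
  if (!is.finite(thresholds$t_r) || !is.finite(thresholds$t_max) ||
      !is.finite(thresholds$t_min))
    stop("thresholds must be initialized (see init_thresholds())",
         call. = FALSE)
  refr <- as.integer(round(config$refractory_window * signal$fs))
  res <- scan_core(signal$samples, diff$values,
                   thresholds$t_max, thresholds$t_min, thresholds$t_r,
                   refr, 1L, length(diff$values),
                   complete = TRUE, first_only = FALSE)
  events_to_frame(res$events)
}

# --- error correction --------------------------------------------------------

#' RR-interval error correction
#'
#' Given a candidate detection and the previous accepted RR interval
#' (`Last_Dif`), decides its fate from `Dif = r_index - last_r_index`:
#' \itemize{
#'   \item `Dif > missed_factor * Last_Dif`: a beat was probably missed in
#'     the gap; the gap is rescanned with all three thresholds reduced to
#'     90% (then 81%, 72.9%, ...) of their current values, up to
#'     `max_redetect` reductions, and any recovered candidates are returned
#'     (action `"redetect"`);
#'   \item `Dif < false_factor * Last_Dif`: the candidate sits too close to
#'     the previous beat and is rejected (action `"reject"`);
#'   \item otherwise action `"accept"`.
#' }
#' The first two accepted beats bypass correction; they seed `Last_Dif`.
#'
#' @param event one candidate event (one-row data.frame or list with
#'   0-based `r_index`).
#' @param state a [detector_state] with `last_r_index` / `last_dif`.
#' @param signal,diff baseline-corrected signal and its difference signal.
#' @param thresholds current [mmt_thresholds].
#' @param config a [detector_config].
#' @return list with `action` ("accept", "reject" or "redetect"),
#'   `recovered` (data.frame of beats found in the gap, 0-based) and
#'   `scale` (threshold scale that recovered them, or `NA`).
#' @export
error_correct <- function(event, state, signal, diff, thresholds,
                          config = detector_config()) {
  empty <- events_to_frame(list())
  if (is.null(state$last_r_index) || is.null(state$last_dif))
    return(list(action = "accept", recovered = empty, scale = NA_real_))
  dif <- event$r_index - state$last_r_index
  if (dif < config$false_factor * state$last_dif)
    return(list(action = "reject", recovered = empty, scale = NA_real_))
  if (dif <= config$missed_factor * state$last_dif)
    return(list(action = "accept", recovered = empty, scale = NA_real_))
  refr <- as.integer(round(config$refractory_window * signal$fs))
  from <- state$last_r_index + 2L            # 0-based open interval -> 1-based
  to <- event$r_index                        # excludes both endpoints
  from <- max(from, 1L)
  to <- min(to, length(diff$values))
  for (k in seq_len(config$max_redetect)) {
    sc <- config$redetect_scale^k
    res <- scan_core(signal$samples, diff$values,
                     thresholds$t_max * sc, thresholds$t_min * sc,
                     thresholds$t_r * sc, refr, from, to,
                     complete = TRUE, first_only = FALSE)
    if (length(res$events))
      return(list(action = "redetect", recovered = events_to_frame(res$events),
                  scale = sc))
  }
  list(action = "redetect", recovered = empty, scale = NA_real_)
}

# --- adaptive threshold update -----------------------------------------------

#' Adaptive threshold update with amplitude-trend freeze
#'
#' After a beat is accepted, each threshold relaxes toward the latest
#' measurement:
#' `t_r <- t_r * rate + R_R * coef * (1 - rate)` and analogously for
#' `t_max` (with `d_s1`) and `t_min` (with `d_s2`). If the R amplitude has
#' moved in the same direction for `trend_freeze_count` consecutive beats
#' (a ramping amplitude, common in exercise), adaptation is suspended until
#' the direction changes, so the thresholds do not chase the trend.
#'
#' @param event accepted event (list or one-row data.frame with
#'   `r_amplitude`, `d_s1`, `d_s2`).
#' @param thresholds current [mmt_thresholds].
#' @param state a [detector_state] (trend bookkeeping lives here).
#' @param config a [detector_config].
#' @return list with updated `thresholds`, `state`, and logical `frozen`.
#' @export
update_thresholds <- function(event, thresholds, state,
                              config = detector_config()) {
  amp <- event$r_amplitude
  if (!is.null(state$prev_amp)) {
    dir <- sign(amp - state$prev_amp)
    if (dir != 0 && dir == state$trend_direction) {
      state$trend_count <- state$trend_count + 1L
    } else if (dir != 0) {
      state$trend_direction <- as.integer(dir)
      state$trend_count <- 1L
    } else {
      state$trend_direction <- 0L
      state$trend_count <- 0L
    }
  }
  frozen <- state$trend_count >= config$trend_freeze_count
  if (!frozen) {
    g <- thresholds$coef * (1 - thresholds$rate)
    thresholds$t_r <- thresholds$t_r * thresholds$rate + amp * g
    thresholds$t_max <- thresholds$t_max * thresholds$rate + event$d_s1 * g
    thresholds$t_min <- thresholds$t_min * thresholds$rate + event$d_s2 * g
  }
  state$prev_amp <- amp
  list(thresholds = thresholds, state = state, frozen = frozen)
}

# --- streaming engine --------------------------------------------------------

# One incremental engine behind detect() and detect_stream(). Keeps the
# filtered, baseline-corrected and difference series as growing buffers,
# finalizes baseline-corrected samples once their (W-1)/2 future window is
# available, and advances a scan cursor over completed threshold runs.
new_mmt_engine <- function(fs, config = detector_config(),
                           coefs = mmt_thresholds(),
                           filt = filter_config(),
                           base = baseline_config(),
                           preprocess = TRUE) {
  e <- new.env(parent = emptyenv())
  e$fs <- fs
  e$cfg <- config
  e$coefs <- coefs
  e$preprocess <- preprocess
  if (preprocess) {
    nd <- design_notch(fs, filt$notch_freq, filt$notch_q)
    e$notch_state <- new_iir2_state(nd$b, nd$a)
    filt <- design_fir(fs, filt)
    e$fir_state <- new_fir_state(filt$fir_coefficients)
  }
  e$w <- baseline_window_length(fs, base)
  e$half <- (e$w - 1L) %/% 2L
  e$xf <- numeric(0)
  e$bc <- numeric(0)
  e$yv <- numeric(0)
  e$n_f <- 0L; e$n_bc <- 0L; e$n_y <- 0L
  e$th <- NULL
  e$cur <- NA_integer_
  e$refr <- as.integer(round(config$refractory_window * fs))
  e$block <- as.integer(10 * fs)
  e$last_r <- NA_integer_                    # 1-based R index of last accept
  e$last_dif <- NA_real_
  e$prev_amp <- NULL
  e$trend_dir <- 0L
  e$trend_count <- 0L
  e$n_acc <- 0L
  e$events <- list()
  class(e) <- "mmt_engine"
  e
}

engine_feed <- function(e, x) {
  x <- as.numeric(x)
  if (!length(x)) return(invisible(e))
  if (e$preprocess) {
    st <- iir2_step(e$notch_state, x)
    e$notch_state <- st$state
    st <- fir_step(e$fir_state, st$y)
    e$fir_state <- st$state
    x <- st$y
  }
  e$xf <- c(e$xf, x)
  e$n_f <- e$n_f + length(x)
  engine_advance(e, flush = FALSE)
  invisible(e)
}

engine_advance <- function(e, flush) {
  # finalize baseline-corrected samples
  k2 <- if (flush) e$n_f else e$n_f - e$half
  if (k2 > e$n_bc) {
    ks <- (e$n_bc + 1L):k2
    res <- numeric(length(ks))
    left <- ks[ks <= e$half]
    mid <- ks[ks > e$half & ks + e$half <= e$n_f]
    right <- ks[ks > e$half & ks + e$half > e$n_f]
    for (k in left)
      res[k - e$n_bc] <- stats::median(e$xf[1:min(e$n_f, k + e$half)])
    if (length(mid)) {
      a <- mid[[1L]] - e$half
      b <- mid[[length(mid)]] + e$half
      mm <- stats::runmed(e$xf[a:b], e$w, endrule = "keep")
      res[mid - e$n_bc] <- mm[mid - a + 1L]
    }
    for (k in right)
      res[k - e$n_bc] <- stats::median(e$xf[max(1L, k - e$half):e$n_f])
    e$bc[ks] <- e$xf[ks] - res
    e$n_bc <- k2
  }
  # extend the difference signal
  ny2 <- e$n_bc - 2L
  if (ny2 > e$n_y) {
    idx <- (e$n_y + 1L):ny2
    d <- e$bc[idx + 2L] - e$bc[idx]
    e$yv[idx] <- sign(d) * d^2
    e$n_y <- ny2
  }
  # initialize thresholds once enough post-warm-up data exists
  if (is.null(e$th)) {
    w0 <- as.integer(round(e$cfg$warmup * e$fs))
    span <- as.integer(round(e$cfg$init_span * e$fs))
    if (e$n_bc >= w0 + span && e$n_y >= w0 + 1L) {
      e$th <- .init_th(e$bc[1:e$n_bc], e$yv[1:e$n_y], e$fs, e$cfg, e$coefs)
      e$cur <- w0 + 1L
    }
  }
  if (!is.null(e$th)) engine_scan(e, flush)
  invisible(e)
}

engine_scan <- function(e, flush) {
  repeat {
    if (e$cur > e$n_y) break
    to_blk <- min(e$n_y, e$cur + e$block - 1L)
    complete <- flush && to_blk == e$n_y
    res <- scan_core(e$bc, e$yv, e$th$t_max, e$th$t_min, e$th$t_r,
                     e$refr, e$cur, to_blk, complete, first_only = TRUE)
    if (length(res$events)) {
      engine_candidate(e, res$events[[1L]])
      e$cur <- res$resume
    } else if (res$resume > e$cur) {
      e$cur <- res$resume
      if (to_blk == e$n_y) break
    } else if (to_blk < e$n_y) {
      e$block <- e$block * 2L                # pathological long run: widen
    } else break
  }
  invisible(e)
}

engine_candidate <- function(e, ev) {
  cfg <- e$cfg
  if (e$n_acc < 2L) {
    engine_accept(e, ev)
    return(invisible(e))
  }
  dif <- ev$r - e$last_r
  if (dif < cfg$false_factor * e$last_dif) return(invisible(e))
  if (dif > cfg$missed_factor * e$last_dif) {
    from <- max(e$last_r + 1L, 1L)
    to <- min(ev$r - 1L, e$n_y)
    for (k in seq_len(cfg$max_redetect)) {
      sc <- cfg$redetect_scale^k
      rr <- scan_core(e$bc, e$yv, e$th$t_max * sc, e$th$t_min * sc,
                      e$th$t_r * sc, e$refr, from, to,
                      complete = TRUE, first_only = FALSE)
      if (length(rr$events)) {
        for (ev2 in rr$events) {
          dif2 <- ev2$r - e$last_r
          if (dif2 >= cfg$false_factor * e$last_dif) engine_accept(e, ev2)
        }
        break
      }
    }
    dif <- ev$r - e$last_r
    if (dif < cfg$false_factor * e$last_dif) return(invisible(e))
  }
  engine_accept(e, ev)
}

engine_accept <- function(e, ev) {
  # Last_Dif tracks the running RR estimate. An interval that still exceeds
  # missed_factor * Last_Dif after redetection is an unexplained gap (a
  # beat lost to noise), not a physiological RR: absorbing it would make
  # the 0.6 rule reject the next true beat, cascading into every other
  # beat being dropped. Such gaps leave Last_Dif unchanged.
  if (e$n_acc >= 1L) {
    dif <- ev$r - e$last_r
    if (is.na(e$last_dif) || dif <= e$cfg$missed_factor * e$last_dif)
      e$last_dif <- dif
  }
  e$last_r <- ev$r
  e$n_acc <- e$n_acc + 1L
  e$events[[length(e$events) + 1L]] <- ev
  st <- detector_state(prev_amp = e$prev_amp, trend_direction = e$trend_dir,
                       trend_count = e$trend_count)
  upd <- update_thresholds(list(r_amplitude = ev$amp, d_s1 = ev$d1,
                                d_s2 = ev$d2),
                           e$th, st, e$cfg)
  e$th <- upd$thresholds
  e$prev_amp <- upd$state$prev_amp
  e$trend_dir <- upd$state$trend_direction
  e$trend_count <- upd$state$trend_count
  invisible(e)
}

engine_flush <- function(e) {
  if (e$n_f < e$w)
    stop("signal (", e$n_f, " samples) is shorter than the baseline ",
         "median window (", e$w, " samples)", call. = FALSE)
  engine_advance(e, flush = TRUE)
  if (is.null(e$th))
    stop("signal too short for threshold initialization: needs ",
         e$cfg$warmup + e$cfg$init_span, " s (warm-up + init span)",
         call. = FALSE)
  events_to_frame(e$events)
}

#' Detect R-waves in a whole signal
#'
#' Runs the full pipeline — notch, FIR low-pass, median baseline
#' correction, signed-square window difference, threshold initialization,
#' adaptive MMT scanning with error correction — over the signal and
#' returns the accepted detections. Indices are 0-based on the processed
#' (filtered) timeline; see [run_pipeline()] for group-delay-compensated
#' indices on the raw timeline.
#'
#' @param signal an [ecg_signal] spanning at least
#'   `warmup + init_span` seconds.
#' @param config a [detector_config].
#' @param thresholds an [mmt_thresholds] carrying the coefficients.
#' @param filter a [filter_config].
#' @param baseline a [baseline_config].
#' @param preprocess set `FALSE` if the signal is already filtered and
#'   baseline-corrected.
#' @return Event data.frame (columns `s1`, `s2`, `r_index`, `r_amplitude`,
#'   `d_s1`, `d_s2`), `r_index` strictly increasing.
#' @export
detect <- function(signal, config = detector_config(),
                   thresholds = mmt_thresholds(),
                   filter = filter_config(),
                   baseline = baseline_config(),
                   preprocess = TRUE) {
  stopifnot(inherits(signal, "ecg_signal"))
  need <- ceiling((config$warmup + config$init_span) * signal$fs)
  if (length(signal$samples) < need + 2L)
    stop("signal too short: detection needs at least ",
         config$warmup + config$init_span, " s of data", call. = FALSE)
  e <- new_mmt_engine(signal$fs, config, thresholds, filter, baseline,
                      preprocess)
  engine_feed(e, signal$samples)
  engine_flush(e)
}

#' Detect R-waves from contiguous chunks
#'
#' Streaming counterpart of [detect()]: feeds the chunks through the same
#' incremental engine, so the concatenated output is event-for-event equal
#' to [detect()] on the concatenated signal, for any chunking. Latency is
#' bounded by the FIR delay plus the baseline half-window plus the
#' refractory window.
#'
#' @param chunks list of [ecg_signal] segments sharing one `fs`, in order.
#' @inheritParams detect
#' @return Event data.frame as for [detect()].
#' @export
detect_stream <- function(chunks, config = detector_config(),
                          thresholds = mmt_thresholds(),
                          filter = filter_config(),
                          baseline = baseline_config(),
                          preprocess = TRUE) {
  if (!length(chunks)) stop("`chunks` must be non-empty", call. = FALSE)
  stopifnot(all(vapply(chunks, inherits, logical(1), "ecg_signal")))
  fs <- chunks[[1L]]$fs
  bad <- which(vapply(chunks, function(s) !identical(s$fs, fs), logical(1)))
  if (length(bad))
    stop("chunk ", bad[[1L]], " has fs = ", chunks[[bad[[1L]]]]$fs,
         " Hz but the stream started at ", fs, " Hz", call. = FALSE)
  e <- new_mmt_engine(fs, config, thresholds, filter, baseline, preprocess)
  for (ch in chunks) engine_feed(e, ch$samples)
  engine_flush(e)
}
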