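# The MMT detector: window difference, threshold initialization, S1/S2
# scanning, error correction, adaptive updates, and the full pipeline.

test_that("window difference is the signed square of the 2-lag slope", {
  fs <- 500
  expect_equal(window_difference(ecg_signal(rep(1, 10), fs))$values,
               rep(0, 8))
  expect_equal(window_difference(ecg_signal(c(1, 2, 5), fs))$values, 16)
  expect_equal(window_difference(ecg_signal(c(5, 2, 1), fs))$values, -16)
  expect_error(window_difference(ecg_signal(c(1, 2), fs)), "3 samples")

  set.seed(4)
  x <- rnorm(60)
  expect_equal(window_difference(ecg_signal(x, fs))$values,
               bf_window_difference(x))
})

test_that("window difference has odd symmetry", {
  set.seed(8)
  for (i in 1:5) {
    x <- cumsum(rnorm(100))
    expect_equal(window_difference(ecg_signal(-x, 500))$values,
                 -window_difference(ecg_signal(x, 500))$values)
  }
})

test_that("threshold initialization applies Xmax*coef1 and Y extrema*coef2", {
  fs <- 100
  x <- numeric(4 * fs)
  x[seq(150, 390, by = 80)] <- 1.0            # post-warm-up peaks of 1 mV
  sig <- ecg_signal(x, fs)
  d <- window_difference(sig)
  th <- init_thresholds(sig, d, detector_config(), mmt_thresholds())
  expect_equal(th$t_r, 0.5 * 1.0)
  expect_equal(th$t_max, 0.4 * max(d$values[101:300]))
  expect_equal(th$t_min, 0.4 * min(d$values[101:300]))
})

test_that("a filter transient inside the warm-up does not inflate T_R", {
  fs <- 100
  x <- numeric(4 * fs)
  x[10] <- 50                                  # huge transient in first 1 s
  x[seq(150, 390, by = 80)] <- 1.0
  sig <- ecg_signal(x, fs)
  th <- init_thresholds(sig, window_difference(sig), detector_config(),
                        mmt_thresholds())
  expect_equal(th$t_r, 0.5)
  expect_error(init_thresholds(ecg_signal(rnorm(100), fs),
                               window_difference(ecg_signal(rnorm(100), fs))),
               "too short")
})

test_that("scan_mmt pairs an up-slope maximum with a down-slope minimum", {
  fs <- 500
  k <- 300                                     # 0-based apex index
  i <- 0:999
  x <- exp(-((i - k)^2) / (2 * 5^2))
  sig <- ecg_signal(x, fs)
  d <- window_difference(sig)
  th <- mmt_thresholds(t_r = 0.5, t_max = 0.4 * max(d$values),
                       t_min = 0.4 * min(d$values))
  ev <- scan_mmt(sig, d, th)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$r_index, k)
  expect_lt(ev$s1, ev$s2)
  expect_gt(ev$r_amplitude, th$t_r)

  # flat signal: nothing crosses
  flat <- ecg_signal(numeric(500), fs)
  expect_equal(nrow(scan_mmt(flat, window_difference(flat), th)), 0)

  # inverted R: the down-slope run comes first, so no S1 < S2 pair exists
  inv <- ecg_signal(-x, fs)
  expect_equal(nrow(scan_mmt(inv, window_difference(inv), th)), 0)

  expect_error(scan_mmt(sig, d, mmt_thresholds()), "initialized")
})

test_that("error correction takes redetect / accept / reject branches", {
  fs <- 500
  flat <- ecg_signal(numeric(3000), fs)
  d <- window_difference(flat)
  th <- mmt_thresholds(t_r = 0.5, t_max = 1, t_min = -1)
  st <- detector_state(last_r_index = 1000L, last_dif = 500)
  branch <- function(dif) {
    error_correct(list(r_index = 1000L + as.integer(dif)), st, flat, d, th,
                  detector_config())
  }
  expect_equal(branch(2.0 * 500)$action, "redetect")
  expect_equal(branch(1.0 * 500)$action, "accept")
  expect_equal(branch(0.5 * 500)$action, "reject")
  # exactly at the boundaries: 0.6 <= ratio <= 1.66 accepts
  expect_equal(branch(0.6 * 500)$action, "accept")
  expect_equal(branch(1.66 * 500)$action, "accept")
  # before Last_Dif exists every candidate is accepted
  expect_equal(error_correct(list(r_index = 1010L), detector_state(),
                             flat, d, th)$action, "accept")
})

test_that("redetection at reduced thresholds recovers a beat in the gap", {
  fs <- 500
  k1 <- 300; k2 <- 600; k3 <- 1200
  i <- 0:1799
  gauss <- function(k, a) a * exp(-((i - k)^2) / (2 * 5^2))
  x <- gauss(k1, 1) + gauss(k2, 1) + gauss(k3, 1)
  x_mid <- gauss(900, 0.62)                    # below both thresholds, in gap
  sig <- ecg_signal(x + x_mid, fs)
  d <- window_difference(sig)
  dm <- window_difference(ecg_signal(gauss(900, 1), fs))
  # attenuated beat: amplitude 0.62 < t_r = 0.7; slope 0.62^2 = 0.384 of the
  # unit beat's, < t_max = 0.4. One 0.9 scaling clears t_max, two clear t_r.
  th <- mmt_thresholds(t_r = 0.7, t_max = 0.4 * max(dm$values),
                       t_min = 0.4 * min(dm$values))
  st <- detector_state(last_r_index = 600L, last_dif = 300)
  res <- error_correct(list(r_index = 1200L), st, sig, d, th,
                       detector_config())
  expect_equal(res$action, "redetect")
  expect_equal(res$recovered$r_index, 900)
  expect_equal(res$scale, 0.9^2)
})

test_that("threshold update follows the rate/coef recursion", {
  st <- detector_state()
  cfg <- detector_config()
  ev <- list(r_amplitude = 2.0, d_s1 = 3.0, d_s2 = -3.0)

  th <- mmt_thresholds(t_r = 1, t_max = 1, t_min = -1, rate = 1)
  expect_equal(update_thresholds(ev, th, st, cfg)$thresholds$t_r, 1)

  th <- mmt_thresholds(t_r = 1, t_max = 1, t_min = -1, rate = 0, coef = 1)
  upd <- update_thresholds(ev, th, st, cfg)
  expect_equal(upd$thresholds$t_r, 2.0)
  expect_equal(upd$thresholds$t_max, 3.0)
  expect_equal(upd$thresholds$t_min, -3.0)

  th <- mmt_thresholds(t_r = 1, t_max = 1, t_min = -1, rate = 0.8,
                       coef = 0.5)
  expect_equal(update_thresholds(ev, th, st, cfg)$thresholds$t_r,
               1 * 0.8 + 2 * 0.5 * 0.2)       # = 1.0
})

test_that("two consecutive same-direction amplitude changes freeze updates", {
  cfg <- detector_config()
  th <- mmt_thresholds(t_r = 0.5, t_max = 1, t_min = -1)
  st <- detector_state()
  amps <- c(1.0, 1.1, 1.2, 1.3, 1.1)
  frozen <- logical(length(amps))
  for (k in seq_along(amps)) {
    upd <- update_thresholds(list(r_amplitude = amps[k], d_s1 = 1,
                                  d_s2 = -1), th, st, cfg)
    th <- upd$thresholds; st <- upd$state; frozen[k] <- upd$frozen
  }
  # third and fourth beats ride an established increasing trend
  expect_equal(frozen, c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("with constant amplitude T_R converges to R*coef", {
  th <- mmt_thresholds(t_r = 5, t_max = 2, t_min = -2)
  st <- detector_state()
  cfg <- detector_config()
  for (k in 1:200) {
    upd <- update_thresholds(list(r_amplitude = 0.8, d_s1 = 1.2,
                                  d_s2 = -1.4), th, st, cfg)
    th <- upd$thresholds; st <- upd$state
  }
  expect_equal(th$t_r, 0.8 * th$coef, tolerance = 1e-9)
  expect_equal(th$t_max, 1.2 * th$coef, tolerance = 1e-9)
  expect_equal(th$t_min, -1.4 * th$coef, tolerance = 1e-9)
})

test_that("full detection finds every beat of a clean record exactly", {
  rec <- clean_record(duration = 30, seed = 2)     # 60 bpm, no jitter
  out <- run_pipeline(rec$signal, pipeline_config())
  fs <- 500
  truth <- rec$truth$r_indices
  truth <- truth[truth >= fs * 1]                  # warm-up span excluded
  expect_equal(nrow(out$events), length(truth))
  expect_true(all(abs(out$events$r_index - truth) <= 1))
})

test_that("50 Hz interference at half the R amplitude leaves detections unchanged", {
  clean <- synth_ecg(synth_config(duration = 30, seed = 13,
                                  r_amp_jitter = 0.08, rr_jitter = 0.04))
  noisy <- synth_ecg(synth_config(duration = 30, seed = 13,
                                  r_amp_jitter = 0.08, rr_jitter = 0.04,
                                  powerline_amp = 0.5))
  a <- run_pipeline(clean$signal, pipeline_config())$events
  b <- run_pipeline(noisy$signal, pipeline_config())$events
  expect_equal(b$r_index, a$r_index)
})

test_that("too-short signals raise an argument error", {
  expect_error(detect(ecg_signal(numeric(0), 500)), "too short")
  expect_error(detect(ecg_signal(rnorm(1000), 500)), "too short")
})

test_that("scaling the signal scales thresholds but not detections", {
  rec <- clean_record(duration = 12, seed = 21)
  fs <- 500
  s1 <- notch_filter(rec$signal); s1 <- fir_lowpass(s1)
  s1 <- baseline_correct(s1)
  d1 <- window_difference(s1)
  th1 <- init_thresholds(s1, d1)
  c <- 2.5
  s2 <- ecg_signal(s1$samples * c, fs)
  d2 <- window_difference(s2)
  th2 <- init_thresholds(s2, d2)
  expect_equal(th2$t_r, c * th1$t_r)
  expect_equal(th2$t_max, c^2 * th1$t_max)
  expect_equal(th2$t_min, c^2 * th1$t_min)

  ev1 <- detect(rec$signal)
  ev2 <- detect(ecg_signal(rec$signal$samples * c, fs))
  expect_equal(ev2$r_index, ev1$r_index)
})

test_that("accepted intervals respect the misjudgment rule", {
  rec <- synth_ecg(synth_preset("exercise", seed = 3))
  ev <- detect(rec$signal)
  r <- ev$r_index
  expect_true(all(diff(r) > 0))
  ld <- NA
  cfg <- detector_config()
  for (k in seq_along(r)[-1]) {
    dif <- r[k] - r[k - 1]
    if (!is.na(ld)) expect_gte(dif, cfg$false_factor * ld)
    if (is.na(ld) || dif <= cfg$missed_factor * ld) ld <- dif
  }
})

test_that("streaming detection matches batch detection chunk-for-chunk", {
  rec <- synth_ecg(synth_config(duration = 20, seed = 5,
                                r_amp_jitter = 0.08, rr_jitter = 0.04,
                                emg_snr_db = 15))
  whole <- detect(rec$signal)
  x <- rec$signal$samples
  # 1 s chunks plus a single-sample chunk wedged in
  chunks <- list(ecg_signal(x[1:5000], 500), ecg_signal(x[5001], 500),
                 ecg_signal(x[5002:length(x)], 500))
  expect_equal(detect_stream(chunks), whole)

  chunks2 <- lapply(split(x, ceiling(seq_along(x) / 500)),
                    ecg_signal, fs = 500)
  names(chunks2) <- NULL
  expect_equal(detect_stream(chunks2), whole)

  bad <- list(ecg_signal(x[1:100], 500), ecg_signal(x[101:200], 360))
  expect_error(detect_stream(bad), "fs")
})
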