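# Beat matching and Se/+P metrics.

test_that("identical detections give perfect counts", {
  ref <- c(100L, 600L, 1100L)
  m <- match_beats(ref, ref, tolerance = 0.15, fs = 500)
  expect_equal(c(m$tp, m$fn, m$fp), c(3L, 0L, 0L))
  expect_equal(m$se, 100)
  expect_equal(m$ppv, 100)
})

test_that("detections shifted beyond tolerance match nothing", {
  ref <- seq(500L, 5000L, by = 500L)
  det <- ref + 2L * 75L + 1L                   # 2x the 75-sample tolerance
  m <- match_beats(det, ref, tolerance = 0.15, fs = 500)
  expect_equal(c(m$tp, m$fn, m$fp),
               c(0L, length(ref), length(det)))
})

test_that("greedy chronological matching resolves the worked example", {
  # tolerance of 10 samples at fs = 1: reference (100, 300),
  # detections (101, 150, 301) -> TP 2, FP 1, FN 0
  m <- match_beats(c(101L, 150L, 301L), c(100L, 300L), tolerance = 10,
                   fs = 1)
  expect_equal(c(m$tp, m$fn, m$fp), c(2L, 0L, 1L))
  expect_equal(m$matched$detection, c(101L, 301L))
})

test_that("counts are conserved and matching ignores sub-tolerance shifts", {
  set.seed(14)
  for (i in 1:20) {
    ref <- cumsum(sample(150:400, 15, replace = TRUE))
    det <- sort(unique(c(ref[runif(15) > 0.2] + sample(-40:40, 1),
                         sample(10000L, 3))))
    m <- match_beats(det, ref, tolerance = 0.15, fs = 360)
    expect_equal(m$tp + m$fn, length(ref))
    expect_equal(m$tp + m$fp, length(det))
  }
  ref <- seq(1000L, 9000L, by = 400L)
  a <- match_beats(ref + 0L, ref, 0.15, 360)
  b <- match_beats(ref + 30L, ref, 0.15, 360)   # 30 < 54-sample tolerance
  expect_equal(b$tp, a$tp)
})

test_that("greedy matching equals exhaustive optimal matching", {
  set.seed(23)
  for (i in 1:25) {
    gaps <- sample(120:300, sample(3:8, 1), replace = TRUE)
    ref <- cumsum(gaps)
    tol <- floor(min(gaps) / 2) - 1            # windows cannot overlap
    det <- sort(unique(c(ref[runif(length(ref)) > 0.3] +
                           sample((-tol):tol, 1),
                         sample(2000L, 2))))
    m <- match_beats(det, ref, tolerance = tol, fs = 1)
    expect_equal(m$tp, bf_match_optimal(ref, det, tol))
  }
})

test_that("metrics come from the count definitions, undefined stays NA", {
  m <- compute_metrics(10, 0, 0)
  expect_equal(c(m$se, m$ppv), c(100, 100))
  m <- compute_metrics(0, 5, 5)
  expect_equal(c(m$se, m$ppv), c(0, 0))
  expect_warning(m <- compute_metrics(0, 0, 5), "Se undefined")
  expect_true(is.na(m$se))
  expect_warning(m <- compute_metrics(0, 5, 0), "undefined")
  expect_true(is.na(m$ppv))
  expect_error(match_beats(c(5L, 3L), c(1L, 2L), 0.1, 100), "increasing")
})

test_that("rounding for reports is half-up at 2 decimals", {
  expect_equal(round_half_up(99.695), 99.70)
  expect_equal(round_half_up(99.69499), 99.69)
  expect_equal(round_half_up(1.005), 1.00)     # fp representation of 1.005
  expect_equal(round_half_up(2.675, 2), 2.68)
})

test_that("evaluate_record scores a synthetic record end to end", {
  rec <- clean_record(duration = 20, seed = 17,
                      r_amp_jitter = 0.08, rr_jitter = 0.04)
  res <- evaluate_record(rec$signal, rec$truth)
  expect_equal(res$fn, 0)
  expect_equal(res$fp, 0)
  expect_equal(res$se, 100)
  expect_equal(res$ppv, 100)
})

test_that("an injected spurious spike is scored as one false positive", {
  rec <- clean_record(duration = 20, seed = 17,
                      r_amp_jitter = 0.08, rr_jitter = 0.04)
  x <- rec$signal$samples
  tt <- rec$truth$r_indices
  # an R-like artifact placed at 70% of an RR interval: far enough from the
  # previous beat to survive the misjudgment rule, so it is accepted
  ctr <- tt[10] + round(0.7 * (tt[11] - tt[10]))
  i <- seq_along(x) - 1L
  x <- x + 1.1 * exp(-((i - ctr)^2) / (2 * 5^2))
  res <- evaluate_record(ecg_signal(x, 500), rec$truth)
  expect_equal(res$fp, 1)
  expect_lte(res$fn, 1)    # the crowded next beat may fall to the 0.6 rule
})

test_that("pooled metrics sum counts rather than averaging percentages", {
  a <- match_beats(c(100L, 300L), c(100L, 300L), 0.15, 360)       # 100%
  b <- match_beats(c(100L), c(100L, 300L, 500L, 700L), 0.15, 360) # 25%
  pooled <- pool_results(list(rec_a = a, rec_b = b))
  expect_equal(pooled$tp, 3)
  expect_equal(pooled$fn, 3)
  expect_equal(pooled$se, 50)                  # not mean(100, 25) = 62.5
  expect_equal(nrow(pooled$per_record), 2)
  expect_equal(pooled$per_record$record, c("rec_a", "rec_b"))
})
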