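upsweep_contours <- function(t0 = 0.5, dur = 1, f0 = 5000, f1 = 15000) {
  proto <- contour_prototype("up", data.frame(
    duration = dur, f0 = f0, f1 = f1, curvature = 0))
  cts <- prototype_contour(proto, t0 = t0, dt = 0.005)
  for (i in seq_along(cts)) attr(cts[[i]], "session_id") <- "S1"
  cts
}

test_that("spectrogram dimensions, axes and degenerate inputs behave", {
  fs <- 96000
  x <- stats::rnorm(fs / 2)
  g <- spectrogram(x, fs, transform_size = 1024L, overlap = 0.5)
  hop <- 512L
  expect_equal(nrow(g$mag), floor((length(x) - 1024L) / hop) + 1L)
  expect_equal(ncol(g$mag), 512L)
  expect_equal(g$f[1L], 0)
  expect_lt(max(g$f), fs / 2)
  expect_equal(g$df, fs / 1024)
  z <- spectrogram(numeric(2048), fs)
  expect_true(all(z$mag == 0))
  expect_error(spectrogram(numeric(100), fs), "shorter")
  expect_error(spectrogram(x, fs, transform_size = 1000L), "power of two")
})

test_that("spectrogram energy matches signal energy under the window normalization", {
  fs <- 96000
  x <- with_seed(5, stats::rnorm(fs))
  g <- spectrogram(x, fs, transform_size = 1024L, overlap = 0.5)
  # sum over frames of |FFT|^2 = N * sum(w^2 x^2); with 50% overlap the
  # squared Hann tiles the signal with density sum(w^2)/hop per sample
  w <- signal::hanning(1024L)
  expected <- 1024 * sum(w^2) / 512 * sum(x^2)
  # one-sided grid: double all bins except DC
  total <- sum(g$mag[, -1L]^2) * 2 + sum(g$mag[, 1L]^2)
  expect_equal(total / expected, 1, tolerance = 0.05)
})

test_that("a clean chirp is traced as one contour within a bin of truth", {
  cts <- upsweep_contours()
  wav <- render_audio(cts, snr_db = 30, seed = 2)
  g <- spectrogram(wav)
  traced <- trace_contours(g)
  expect_length(traced, 1L)
  ct <- traced[[1L]]
  truef <- stats::approx(cts[[1L]]$t, cts[[1L]]$f, xout = ct$t,
                         rule = 2)$y
  expect_lte(stats::median(abs(ct$f - truef)), g$df)
  expect_lt(max(abs(ct$f - truef)), 2 * g$df)
  expect_lt(abs(ct$t[1L] - 0.5), g$dt)
  # rerun is bit-identical
  expect_identical(serialize(traced, NULL),
                   serialize(trace_contours(g), NULL))
})

test_that("separated whistles yield separate contours with correct onsets", {
  cts <- c(upsweep_contours(t0 = 0.5), upsweep_contours(t0 = 3.5))
  wav <- render_audio(cts, snr_db = 30, seed = 3)
  g <- spectrogram(wav)
  traced <- trace_contours(g)
  expect_length(traced, 2L)
  starts <- sort(vapply(traced, function(ct) ct$t[1L], numeric(1L)))
  expect_lt(abs(starts[1L] - 0.5), g$dt)
  expect_lt(abs(starts[2L] - 3.5), g$dt)
})

test_that("grades are monotone in SNR and extreme SNRs hit grades 3 and 1", {
  cts <- upsweep_contours()
  grade_at <- function(snr) {
    wav <- render_audio(cts, snr_db = snr, seed = 4)
    traced <- trace_contours(spectrogram(wav))
    if (!length(traced)) return(0L)  # below detection: effectively discarded
    max(vapply(traced, function(ct) ct$grade, integer(1L)))
  }
  snrs <- c(2, 6, 12, 16, 25, 35)
  grades <- vapply(snrs, grade_at, integer(1L))
  expect_true(all(diff(grades) >= 0L))
  expect_identical(grades[length(grades)], 3L)
  expect_lte(grades[1L], 1L)
  wav30 <- render_audio(cts, snr_db = 30, seed = 4)
  ct30 <- trace_contours(spectrogram(wav30))[[1L]]
  expect_identical(ct30$grade, 3L)
  expect_equal(ct30$snr, 30, tolerance = 0.15)
})

test_that("extraction recovers every clean whistle with no spurious contours", {
  # seeded suite of clean (30 dB) two-whistle scenes
  pool <- oracle_prototype_pool()
  n_missed <- 0L; n_spurious <- 0L
  for (seed in 1:25) {
    set.seed(seed)
    ids <- sample(names(pool), 2L)
    cts <- list()
    t0 <- 0.5
    truth_n <- 0L
    for (id in ids) {
      loops <- prototype_contour(pool[[id]], t0 = t0, dt = 0.005)
      for (lp in loops) {
        attr(lp, "session_id") <- "S1"
        cts[[length(cts) + 1L]] <- lp
      }
      truth_n <- truth_n + length(loops)
      t0 <- max(loops[[length(loops)]]$t) + runif(1, 1.5, 3)
    }
    wav <- render_audio(cts, snr_db = 30, seed = seed)
    traced <- trace_contours(spectrogram(wav))
    n_missed <- n_missed + max(0L, truth_n - length(traced))
    n_spurious <- n_spurious + max(0L, length(traced) - truth_n)
  }
  expect_identical(n_missed, 0L)
  expect_identical(n_spurious, 0L)
})

test_that("extract_whistles drops grade-1 contours and logs attrition", {
  cts <- upsweep_contours()
  wav <- render_audio(cts, snr_db = 5, seed = 6)
  kept <- extract_whistles(wav)
  expect_length(kept, 0L)
  expect_gte(attr(kept, "n_discarded"), 0L)
  wav2 <- render_audio(cts, snr_db = 30, seed = 6)
  kept2 <- extract_whistles(wav2)
  expect_length(kept2, 1L)
  expect_identical(attr(kept2, "n_traced"), 1L)
})
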