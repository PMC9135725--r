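contour_from <- function(t, f) {
  structure(list(t = t, f = f, identity = NA_character_),
            class = "sw_contour", session_id = "S1")
}

test_that("analytic contours yield exact seven-parameter vectors", {
  # linear upsweep 5 -> 15 kHz over 1 s
  tt <- seq(0, 1, by = 0.005)
  up <- contour_from(tt, 5000 + 10000 * tt)
  fv <- measure_features(up)
  expect_equal(unlist(fv), c(min_freq = 5000, max_freq = 15000,
                             start_freq = 5000, end_freq = 15000,
                             freq_range = 10000, n_inflections = 0,
                             duration = 1))
  # symmetric chevron over 2 s
  t2 <- seq(0, 2, by = 0.005)
  chev <- contour_from(t2, 5000 + 10000 * (1 - abs(t2 - 1)))
  fv2 <- measure_features(chev)
  expect_equal(unlist(fv2), c(min_freq = 5000, max_freq = 15000,
                              start_freq = 5000, end_freq = 5000,
                              freq_range = 10000, n_inflections = 1,
                              duration = 2))
  # sinusoidal FM, 3 full periods: 6 slope sign changes
  t3 <- seq(0, 1.5, by = 0.002)
  sine <- contour_from(t3, 10000 + 3000 * sin(2 * pi * 2 * t3))
  fv3 <- measure_features(sine)
  expect_identical(fv3$n_inflections, 6L)
  expect_equal(fv3$max_freq, 13000, tolerance = 1e-3)
  expect_equal(fv3$min_freq, 7000, tolerance = 1e-3)
})

test_that("multi-loop units are measured across loops, gaps included", {
  proto <- contour_prototype("two", data.frame(
    duration = 0.5, f0 = 6000, f1 = 12000, curvature = 0),
    n_loops = 3L, inter_loop_gap = 0.2)
  unit <- merge_loops(prototype_contour(proto, dt = 0.005))[[1L]]
  fv <- measure_features(unit)
  expect_equal(fv$duration, 3 * 0.5 + 2 * 0.2)
  expect_equal(fv$start_freq, 6000)
  expect_equal(fv$end_freq, 12000)
  expect_identical(fv$n_inflections, 0L)  # gaps create no inflections
})

test_that("smoothing suppresses sub-scale jitter but keeps real inflections", {
  tt <- seq(0, 1, by = 0.005)
  base <- 5000 + 10000 * tt
  jit <- rep_len(c(-40, 40), length(tt))
  expect_identical(count_inflections(tt, base + jit, smooth_window = 5L),
                   0L)
  expect_gt(count_inflections(tt, base + jit, smooth_window = 1L), 0L)
  chev <- 5000 + 10000 * (1 - abs(tt - 0.5) * 2)
  expect_identical(count_inflections(tt, chev + jit, smooth_window = 5L),
                   1L)
  # invariant to a uniform frequency offset
  expect_identical(count_inflections(tt, base + jit + 3000, 5L),
                   count_inflections(tt, base + jit, 5L))
})

test_that("degenerate contours are rejected", {
  expect_error(measure_features(contour_from(0.1, 5000)), "degenerate")
  expect_error(count_inflections(c(0, 1), c(5000, 6000)), "three")
})

test_that("the frequency-range identity holds on every generated vector", {
  study <- make_repertoire(sw_per_site = 2, seed = 13,
                           effects = reference_effects())
  ft <- simulate_feature_study(study, obs_per_id = 3, seed = 14)
  expect_equal(ft$freq_range, ft$max_freq - ft$min_freq)
  expect_true(all(ft$min_freq <= pmin(ft$start_freq, ft$end_freq)))
  expect_true(all(ft$max_freq >= pmax(ft$start_freq, ft$end_freq)))
  expect_true(all(ft$duration > 0))
  expect_true(all(ft$n_inflections >= 0))
})

test_that("features measured after rendering and extraction stay within one bin and one hop", {
  proto <- with_seed(1, make_prototype_from_features(
    "p", min_freq = 6000, max_freq = 16000, start_freq = 8000,
    end_freq = 9000, duration = 1, n_inflections = 3))
  truth <- prototype_features(proto)
  cts <- prototype_contour(proto, t0 = 0.5, dt = 0.005)
  for (i in seq_along(cts)) attr(cts[[i]], "session_id") <- "S1"
  wav <- render_audio(cts, snr_db = 30, seed = 2)
  g <- spectrogram(wav)
  unit <- merge_loops(trace_contours(g))[[1L]]
  meas <- measure_features(unit)
  for (nm in c("min_freq", "max_freq", "start_freq", "end_freq"))
    expect_lt(abs(meas[[nm]] - truth[[nm]]), g$df)
  expect_lt(abs(meas$duration - truth$duration), g$dt)
  expect_identical(meas$n_inflections, truth$n_inflections)
})
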