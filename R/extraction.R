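#' Compute a magnitude spectrogram
#'
#' Short-time Fourier magnitude grid in the convention used throughout the
#' package: rows are time frames (frame-center timestamps), columns are
#' frequency bins from 0 to just below Nyquist. Defaults follow the
#' analysis settings for 96 kHz recordings: 1024-point FFT (93.75 Hz bins),
#' Hann window, 50% overlap; 512-point transforms are equally supported for
#' lower sampling rates.
#'
#' @param waveform An `sw_waveform` from [render_audio()], or a numeric
#'   sample vector (then `sample_rate` must be given).
#' @param sample_rate Sampling rate in Hz.
#' @param transform_size FFT size in samples; must be a power of two.
#' @param window Window name: `"hann"` or `"hamming"`.
#' @param overlap Overlap fraction in \[0, 1).
#' @return An object of class `sw_tfgrid`: `mag` (time x frequency
#'   magnitude matrix), `t` (frame centers, s), `f` (bin centers, Hz),
#'   `dt` (hop, s), `df` (bin width, Hz), `window`, `overlap`,
#'   `window_values`.
#' @export
spectrogram <- function(waveform, sample_rate = NULL,
                        transform_size = 1024L, window = "hann",
                        overlap = 0.5) {
  if (inherits(waveform, "sw_waveform")) {
    sample_rate <- waveform$sample_rate
    waveform <- waveform$samples
  }
  if (is.null(sample_rate)) stop("sample_rate is required")
  transform_size <- as.integer(transform_size)
  if (bitwAnd(transform_size, transform_size - 1L) != 0L)
    stop("transform_size must be a power of two")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (length(waveform) < transform_size)
    stop("waveform shorter than one transform window (",
         length(waveform), " < ", transform_size, " samples)")
  w <- switch(window,
              hann = signal::hanning(transform_size),
              hamming = signal::hamming(transform_size),
              stop("unsupported window: ", window))
  hop <- transform_size - floor(transform_size * overlap)
  sp <- signal::specgram(waveform, n = transform_size, Fs = sample_rate,
                         window = w, overlap = transform_size - hop)
  mag <- t(Mod(sp$S))  # frames x bins
  centers <- sp$t + (transform_size - 1) / (2 * sample_rate)
  structure(list(mag = mag, t = as.numeric(centers),
                 f = as.numeric(sp$f), dt = hop / sample_rate,
                 df = sample_rate / transform_size, window = window,
                 overlap = overlap, window_values = w),
            class = "sw_tfgrid")
}

#' @export
print.sw_tfgrid <- function(x, ...) {
  cat(sprintf(
    "Time-frequency grid: %d frames x %d bins (dt = %.4f s, df = %.1f Hz, %s window, %.0f%% overlap)\n",
    nrow(x$mag), ncol(x$mag), x$dt, x$df, x$window, 100 * x$overlap))
  invisible(x)
}

#' Contour extraction parameters
#'
#' The automated, deterministic surrogate for expert spectrogram
#' annotation: per-frame ridge peaks above an onset threshold are chained
#' into contours subject to a maximum frequency jump and a maximum silent
#' gap, and short detections are dropped. All thresholds are exposed here.
#'
#' @param band Analysis band in Hz. Tracing is restricted to this band;
#'   the 22 kHz ceiling keeps contours comparable across recordings made
#'   at 44 kHz and higher sampling rates.
#' @param onset_db Detection threshold in dB above the median in-band
#'   noise floor.
#' @param max_jump_bins Maximum ridge jump between consecutive frames, in
#'   frequency bins. The default of 10 bins/frame (about 175 kHz/s at a
#'   1024-point transform on 96 kHz audio with 50% overlap) accommodates
#'   the steep sweep rates of whistle contours; tighter values break fast
#'   chirps into fragments.
#' @param max_gap_frames Maximum run of silent frames bridged within one
#'   contour.
#' @param min_duration Minimum contour duration in seconds.
#' @param grade3_snr,grade2_snr SNR thresholds (dB, in-band scale) for
#'   quality grades 3 and 2.
#' @param grade3_coverage,grade2_coverage Minimum ridge coverage (fraction
#'   of frames inside the contour span with a detected peak) for grades 3
#'   and 2.
#' @return A list of class `extraction_params`.
#' @export
extraction_params <- function(band = c(2000, 22000), onset_db = 10,
                              max_jump_bins = 10L, max_gap_frames = 3L,
                              min_duration = 0.1, grade3_snr = 20,
                              grade2_snr = 10, grade3_coverage = 0.95,
                              grade2_coverage = 0.90) {
  structure(list(band = band, onset_db = onset_db,
                 max_jump_bins = as.integer(max_jump_bins),
                 max_gap_frames = as.integer(max_gap_frames),
                 min_duration = min_duration, grade3_snr = grade3_snr,
                 grade2_snr = grade2_snr, grade3_coverage = grade3_coverage,
                 grade2_coverage = grade2_coverage),
            class = "extraction_params")
}

#' Trace tonal contours on a spectrogram
#'
#' Deterministic per-frame peak-ridge tracking: in every frame the in-band
#' magnitude peak is detected if it exceeds the onset threshold over the
#' median noise floor; detections in consecutive frames are chained into a
#' contour while the frequency jump stays within `max_jump_bins` per frame
#' and silent interruptions do not exceed `max_gap_frames`. Peak
#' frequencies are refined by parabolic interpolation over the log
#' magnitudes of the three bins around the peak. Contours shorter than
#' `min_duration` are discarded. Each contour carries an in-band SNR
#' estimate (tone power against total in-band noise power, window
#' corrected, in dB) and its ridge coverage, from which the quality grade
#' is assigned (see [grade_whistle()]).
#'
#' @param grid An [spectrogram()] grid.
#' @param params An [extraction_params()] list.
#' @param session_id Session label attached to the traced contours.
#' @return A list of `sw_contour` objects (possibly empty), each with
#'   fields `t`, `f`, `snr`, `coverage`, `grade`.
#' @export
trace_contours <- function(grid, params = extraction_params(),
                           session_id = "S1") {
  stopifnot(inherits(grid, "sw_tfgrid"))
  in_band <- grid$f >= params$band[1L] & grid$f <= params$band[2L]
  if (!any(in_band)) stop("analysis band outside the grid's frequency range")
  mag <- grid$mag[, in_band, drop = FALSE]
  fbin <- grid$f[in_band]
  pow_db <- 10 * log10(mag^2 + .Machine$double.xmin)
  floor_db <- stats::median(pow_db)
  thresh <- floor_db + params$onset_db
  peak_bin <- max.col(pow_db, ties.method = "first")
  peak_db <- pow_db[cbind(seq_len(nrow(pow_db)), peak_bin)]
  active <- peak_db >= thresh
  # window-aware correction from per-bin peak excess to in-band SNR:
  # a sinusoid at bin center has peak power (A sum(w) / 2)^2 while a noise
  # bin has mean power sigma^2 sum(w^2) and median ln(2) times that.
  w <- grid$window_values
  band_frac <- (params$band[2L] - params$band[1L]) /
    (grid$f[length(grid$f)] + grid$df)
  snr_corr <- 10 * log10(sum(w)^2 / (2 * sum(w^2)) * band_frac / log(2))
  contours <- list()
  cur <- NULL
  close_cur <- function(cur) {
    if (is.null(cur)) return(NULL)
    idx <- cur$frames
    dur <- grid$t[idx[length(idx)]] - grid$t[idx[1L]]
    if (dur < params$min_duration) return(NULL)
    span <- idx[length(idx)] - idx[1L] + 1L
    structure(list(
      t = grid$t[idx], f = cur$freqs,
      snr = stats::median(peak_db[idx]) - floor_db - snr_corr,
      coverage = length(idx) / span,
      grade = NA_integer_, identity = NA_character_),
      class = "sw_contour", session_id = session_id)
  }
  last_frame <- -Inf; last_bin <- NA_real_
  for (fr in seq_along(active)) {
    if (!active[fr]) next
    b <- peak_bin[fr]
    f_hat <- parabolic_peak(pow_db[fr, ], b, fbin, grid$df)
    gap <- fr - last_frame - 1L
    jump_ok <- !is.na(last_bin) &&
      abs(b - last_bin) <= params$max_jump_bins * (gap + 1L)
    if (!is.null(cur) && gap <= params$max_gap_frames && jump_ok) {
      cur$frames <- c(cur$frames, fr)
      cur$freqs <- c(cur$freqs, f_hat)
    } else {
      cc <- close_cur(cur)
      if (!is.null(cc)) contours[[length(contours) + 1L]] <- cc
      cur <- list(frames = fr, freqs = f_hat)
    }
    last_frame <- fr; last_bin <- b
  }
  cc <- close_cur(cur)
  if (!is.null(cc)) contours[[length(contours) + 1L]] <- cc
  lapply(contours, function(ct) {
    ct$grade <- grade_whistle(ct, params = params)
    ct
  })
}

# Parabolic interpolation of the peak position over log magnitudes.
parabolic_peak <- function(row_db, b, fbin, df) {
  if (b <= 1L || b >= length(row_db)) return(fbin[b])
  a <- row_db[b - 1L]; m <- row_db[b]; c <- row_db[b + 1L]
  denom <- a - 2 * m + c
  if (denom == 0) return(fbin[b])
  delta <- 0.5 * (a - c) / denom
  fbin[b] + max(min(delta, 0.5), -0.5) * df
}

#' Grade a traced whistle
#'
#' Assigns the three-level quality grade from the contour's SNR estimate
#' and ridge coverage: grade 3 ("whistle predominant") requires SNR above
#' `grade3_snr` and near-complete ridge coverage; grade 2 ("audible,
#' contour clearly visible start to end") relaxes both; everything else is
#' grade 1 ("contour not clearly discernible") and is excluded from all
#' downstream analyses. The grade is monotone in SNR and deterministic.
#'
#' @param contour A traced `sw_contour` carrying `snr` and `coverage`.
#' @param grid Unused; accepted so graders can be swapped for variants
#'   that re-measure the grid.
#' @param params An [extraction_params()] list with the grade thresholds.
#' @return Integer grade 1, 2 or 3.
#' @export
grade_whistle <- function(contour, grid = NULL,
                          params = extraction_params()) {
  snr <- contour$snr %||% -Inf
  cov <- contour$coverage %||% 0
  if (snr > params$grade3_snr && cov >= params$grade3_coverage) return(3L)
  if (snr > params$grade2_snr && cov >= params$grade2_coverage) return(2L)
  1L
}

#' Extract graded contours from session audio
#'
#' Convenience wrapper: spectrogram, ridge tracing and grading in one call,
#' with grade-1 whistles discarded (they are returned in the `discarded`
#' attribute so attrition can be logged).
#'
#' @param waveform An `sw_waveform` or sample vector.
#' @param sample_rate Sampling rate (Hz) when a bare vector is given.
#' @param params [extraction_params()].
#' @param transform_size,window,overlap Passed to [spectrogram()].
#' @param session_id Session label.
#' @return List of graded `sw_contour` objects (grades 2-3), with
#'   attributes `n_traced` and `n_discarded`.
#' @export
extract_whistles <- function(waveform, sample_rate = NULL,
                             params = extraction_params(),
                             transform_size = 1024L, window = "hann",
                             overlap = 0.5, session_id = "S1") {
  grid <- spectrogram(waveform, sample_rate, transform_size, window,
                      overlap)
  all_ct <- trace_contours(grid, params, session_id = session_id)
  grades <- vapply(all_ct, function(ct) ct$grade, integer(1L))
  keep <- all_ct[grades > 1L]
  attr(keep, "n_traced") <- length(all_ct)
  attr(keep, "n_discarded") <- sum(grades == 1L)
  keep
}

#' Write traced contours to CSV
#'
#' @param contours List of `sw_contour` objects.
#' @param path Output CSV path (`session_id`, `contour_id`, `t`, `f`,
#'   `grade`, `snr`).
#' @return The written data frame, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    data.frame(session_id = attr(ct, "session_id") %||% "S1",
               contour_id = i, t = ct$t, f = ct$f,
               grade = ct$grade %||% NA_integer_,
               snr = ct$snr %||% NA_real_)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
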