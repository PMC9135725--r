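#' Render a session's whistles to a waveform
#'
#' Synthesizes each contour as a frequency-modulated tone (phase obtained
#' by integrating the instantaneous frequency, with a short raised-cosine
#' onset/offset ramp to avoid spectral splatter) and adds white Gaussian
#' background noise at the requested signal-to-noise ratio. SNR is defined
#' as the ratio of tonal RMS to the RMS of the noise falling inside the
#' whistle analysis band, in dB; `snr_db = -Inf` is a noise-only sentinel
#' (no tones are rendered).
#'
#' @param session An `sw_session` from [sample_session()], or a bare list
#'   of `sw_contour` objects.
#' @param sample_rate Sampling rate in Hz; must exceed twice the highest
#'   contour frequency.
#' @param snr_db Per-whistle in-band signal-to-noise ratio in dB.
#' @param band Analysis band (Hz) used to define the in-band noise RMS.
#' @param amplitude Peak amplitude of each tone before mixing.
#' @param duration Waveform duration in seconds; defaults to the last
#'   contour end plus half a second.
#' @param ramp Onset/offset ramp length in seconds.
#' @param seed Integer seed for the noise realization.
#' @return A list of class `sw_waveform`: `samples` (numeric vector in
#'   \[-1, 1\]), `sample_rate`, `snr_db`, `band`.
#' @export
render_audio <- function(session, sample_rate = 96000, snr_db = 30,
                         band = c(2000, 22000), amplitude = 0.25,
                         duration = NULL, ramp = 0.002, seed = NULL) {
  contours <- if (inherits(session, "sw_session")) session$contours
              else session
  nyq <- sample_rate / 2
  for (ct in contours) {
    if (max(ct$f) >= nyq)
      stop("contour of '", ct$identity %||% "?",
           "' reaches ", round(max(ct$f)), " Hz, at or above the Nyquist ",
           "frequency (", nyq, " Hz)")
  }
  t_max <- if (length(contours))
    max(vapply(contours, function(ct) max(ct$t), numeric(1L))) else 0
  duration <- duration %||% (t_max + 0.5)
  n <- ceiling(duration * sample_rate)
  x <- numeric(n)
  tonal <- is.finite(snr_db)
  if (tonal) {
    for (ct in contours) {
      i0 <- floor(ct$t[1L] * sample_rate) + 1L
      i1 <- min(ceiling(ct$t[length(ct$t)] * sample_rate), n)
      if (i1 <= i0) next
      tt <- (seq(i0, i1) - 1L) / sample_rate
      f_inst <- stats::approx(ct$t, ct$f, xout = tt, rule = 2)$y
      phase <- 2 * pi * cumsum(f_inst) / sample_rate
      env <- rep(1, length(tt))
      nr <- min(floor(ramp * sample_rate), floor(length(tt) / 2))
      if (nr > 0L) {
        r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
        env[seq_len(nr)] <- r
        env[length(env) - nr + seq_len(nr)] <- rev(r)
      }
      x[i0:i1] <- x[i0:i1] + amplitude * env * sin(phase)
    }
  }
  with_seed(seed, {
    tone_rms <- amplitude / sqrt(2)
    band_frac <- (band[2L] - band[1L]) / nyq
    sigma <- if (is.finite(snr_db)) {
      tone_rms / 10^(snr_db / 20) / sqrt(band_frac)
    } else 0.05
    if (sigma > 0) x <- x + stats::rnorm(n, 0, sigma)
    peak <- max(abs(x))
    if (peak > 0.99) x <- x * (0.99 / peak)
    structure(list(samples = x, sample_rate = sample_rate,
                   snr_db = snr_db, band = band),
              class = "sw_waveform")
  })
}

#' Minimal PCM WAV input/output
#'
#' Writes and reads uncompressed mono PCM RIFF/WAVE files (16- or 24-bit),
#' the interchange format for session audio.
#'
#' @param x Numeric vector of samples in \[-1, 1\], or an `sw_waveform`.
#' @param path File path.
#' @param sample_rate Sampling rate in Hz (taken from the waveform object
#'   if one is given).
#' @param bits Bits per sample: 16 or 24.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns a
#'   list with `samples` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
write_wav <- function(x, path, sample_rate = 96000, bits = 16L) {
  if (inherits(x, "sw_waveform")) { sample_rate <- x$sample_rate; x <- x$samples }
  stopifnot(bits %in% c(16L, 24L))
  x <- pmin(pmax(x, -1), 1)
  bytes_per <- bits / 8L
  n <- length(x)
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4L,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  scale <- 2^(bits - 1L) - 1L
  q <- as.integer(round(x * scale))
  if (bits == 16L) {
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    q[q < 0L] <- q[q < 0L] + as.integer(2^24)
    b <- rbind(q %% 256L, (q %/% 256L) %% 256L, (q %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4L) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4L, endian = "little"))
  if (readChar(con, 4L) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2L, size = 2L, endian = "little")
      if (fmt[1L] != 1L) stop("only PCM WAV is supported")
      if (fmt[2L] != 1L) stop("only mono WAV is supported")
      sample_rate <- readBin(con, integer(), size = 4L, endian = "little")
      invisible(readBin(con, integer(), size = 4L, endian = "little"))
      invisible(readBin(con, integer(), size = 2L, endian = "little"))
      bits <- readBin(con, integer(), size = 2L, endian = "little")
      if (size > 16L) invisible(readBin(con, raw(), n = size - 16L))
    } else if (id == "data") {
      if (bits == 16L) {
        samples <- readBin(con, integer(), n = size / 2L, size = 2L,
                           endian = "little") / (2^15 - 1)
      } else if (bits == 24L) {
        b <- as.integer(readBin(con, raw(), n = size))
        q <- b[c(TRUE, FALSE, FALSE)] + 256L * b[c(FALSE, TRUE, FALSE)] +
          65536L * b[c(FALSE, FALSE, TRUE)]
        q[q >= 2^23] <- q[q >= 2^23] - 2^24
        samples <- q / (2^23 - 1)
      } else stop("unsupported bit depth: ", bits)
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  list(samples = samples, sample_rate = sample_rate)
}
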