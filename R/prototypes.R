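#' Contour prototypes
#'
#' A contour prototype describes the stereotyped frequency-modulation
#' pattern of one whistle type: a sequence of frequency segments, a loop
#' count (signature whistles are often produced as repeated loops separated
#' by short silent gaps), and the gap between loops. Each segment is a
#' quadratic frequency trajectory
#' \deqn{f(u) = f_0 + (f_1 - f_0)\,u + c\,u(1-u), \quad u \in [0, 1],}
#' which degenerates to a linear chirp when the curvature \eqn{c = 0}.
#' This family has closed-form extrema and inflection (slope sign-change)
#' counts, so ground-truth acoustic parameters of every prototype are known
#' exactly.
#'
#' @param identity Label of the whistle type (e.g. an emitter identity).
#' @param segments Data frame with columns `duration` (s), `f0`, `f1` (Hz)
#'   and `curvature` (Hz); one row per segment, played in order.
#' @param n_loops Number of loops (repetitions of the full segment
#'   sequence); must be >= 1.
#' @param inter_loop_gap Silent gap between consecutive loops, in seconds.
#'   Must be non-negative, and should stay below the 0.25 s loop-merging
#'   threshold if the loops are meant to form one multi-loop whistle unit.
#' @return An object of class `contour_prototype`.
#' @seealso [prototype_features()], [prototype_contour()],
#'   [make_prototype_from_features()]
#' @export
contour_prototype <- function(identity, segments, n_loops = 1L,
                              inter_loop_gap = 0.15) {
  stopifnot(is.character(identity), length(identity) == 1L)
  segments <- as.data.frame(segments)
  required <- c("duration", "f0", "f1", "curvature")
  if (!all(required %in% names(segments)))
    stop("segments must have columns: ", paste(required, collapse = ", "))
  if (nrow(segments) < 1L) stop("at least one segment is required")
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  freqs <- segment_extremes(segments)
  if (any(freqs <= 0))
    stop("prototype '", identity, "' has non-positive frequencies")
  n_loops <- as.integer(n_loops)
  if (n_loops < 1L) stop("n_loops must be >= 1")
  if (inter_loop_gap < 0) stop("inter_loop_gap must be >= 0")
  structure(
    list(identity = identity, segments = segments, n_loops = n_loops,
         inter_loop_gap = inter_loop_gap),
    class = "contour_prototype")
}

#' @export
print.contour_prototype <- function(x, ...) {
  fts <- prototype_features(x)
  cat("Contour prototype '", x$identity, "': ", nrow(x$segments),
      " segment(s), ", x$n_loops, " loop(s)\n", sep = "")
  cat(sprintf("  %.0f-%.0f Hz, %.2f s, %d inflection(s)\n",
              fts$min_freq, fts$max_freq, fts$duration, fts$n_inflections))
  invisible(x)
}

# Frequency of one segment at normalized time u in [0, 1].
segment_freq <- function(f0, f1, curvature, u) {
  f0 + (f1 - f0) * u + curvature * u * (1 - u)
}

# All candidate extreme frequencies of a segment table: endpoints plus any
# interior stationary point of the quadratic.
segment_extremes <- function(segments) {
  out <- c(segments$f0, segments$f1)
  c0 <- segments$curvature != 0
  if (any(c0)) {
    us <- ((segments$f1[c0] - segments$f0[c0]) / segments$curvature[c0] + 1) / 2
    keep <- us > 0 & us < 1
    if (any(keep)) {
      s <- segments[c0, ][keep, ]
      out <- c(out, segment_freq(s$f0, s$f1, s$curvature, us[keep]))
    }
  }
  out
}

# Closed-form slope sign-change count over one loop. The slope of a segment
# is s(u) = (f1 - f0) + c (1 - 2u): linear in u, so its sign over the
# segment is captured by the entry and exit values.
loop_inflections <- function(segments) {
  slopes <- c(rbind((segments$f1 - segments$f0) + segments$curvature,
                    (segments$f1 - segments$f0) - segments$curvature))
  slopes <- slopes[slopes != 0]
  if (length(slopes) < 2L) return(0L)
  sum(diff(sign(slopes)) != 0)
}

#' Closed-form acoustic parameters of a prototype
#'
#' Computes the seven whistle parameters of a prototype analytically, over
#' the full multi-loop unit: extrema are taken across all segments, start
#' and end are the first and last segment endpoints, duration includes the
#' inter-loop gaps, and inflection points are slope sign changes summed over
#' loops (the silent gaps between loops do not create inflections).
#'
#' @param proto A [contour_prototype()].
#' @return One-row data frame with columns `min_freq`, `max_freq`,
#'   `start_freq`, `end_freq`, `freq_range`, `n_inflections`, `duration`.
#' @export
prototype_features <- function(proto) {
  stopifnot(inherits(proto, "contour_prototype"))
  ext <- segment_extremes(proto$segments)
  loop_dur <- sum(proto$segments$duration)
  data.frame(
    min_freq = min(ext),
    max_freq = max(ext),
    start_freq = proto$segments$f0[1L],
    end_freq = proto$segments$f1[nrow(proto$segments)],
    freq_range = max(ext) - min(ext),
    n_inflections = proto$n_loops * loop_inflections(proto$segments),
    duration = proto$n_loops * loop_dur +
      (proto$n_loops - 1L) * proto$inter_loop_gap)
}

#' Sample the time-frequency trajectory of a prototype
#'
#' Evaluates the prototype's frequency trajectory on a regular time grid.
#' Segment boundaries are always included as sample points, so piecewise
#' extrema are attained exactly by the sampled contour. Each loop yields one
#' traced contour (loops are separated by silent gaps and are therefore
#' distinct contours until merged into a whistle unit).
#'
#' @param proto A [contour_prototype()].
#' @param t0 Absolute start time of the first loop, in seconds.
#' @param dt Sampling step of the contour, in seconds.
#' @return A list with one element per loop, each an object of class
#'   `sw_contour`: a list with numeric vectors `t` (s) and `f` (Hz) plus the
#'   originating `identity`.
#' @export
prototype_contour <- function(proto, t0 = 0, dt = 0.005) {
  stopifnot(inherits(proto, "contour_prototype"), dt > 0)
  seg <- proto$segments
  # one loop, relative time
  ts <- fs <- vector("list", nrow(seg))
  off <- 0
  for (i in seq_len(nrow(seg))) {
    n <- max(2L, ceiling(seg$duration[i] / dt) + 1L)
    u <- seq(0, 1, length.out = n)
    ti <- off + u * seg$duration[i]
    fi <- segment_freq(seg$f0[i], seg$f1[i], seg$curvature[i], u)
    if (i > 1L) { ti <- ti[-1L]; fi <- fi[-1L] }  # dedupe the joint
    ts[[i]] <- ti; fs[[i]] <- fi
    off <- off + seg$duration[i]
  }
  loop_t <- unlist(ts); loop_f <- unlist(fs)
  loop_dur <- sum(seg$duration)
  lapply(seq_len(proto$n_loops), function(l) {
    start <- t0 + (l - 1L) * (loop_dur + proto$inter_loop_gap)
    structure(list(t = start + loop_t, f = loop_f,
                   identity = proto$identity),
              class = "sw_contour")
  })
}

#' Build a prototype attaining a target parameter vector
#'
#' Constructs a piecewise-linear contour whose seven acoustic parameters
#' are exactly the requested targets. The contour runs from `start_freq`
#' through `n_inflections` alternating interior extrema (one of which is
#' pinned at `max_freq` and one at `min_freq`) to `end_freq`. With
#' `n_inflections >= 2` the minimum and maximum are free of the start/end
#' frequencies; with 0 or 1 inflections the targets must be consistent with
#' a monotone or single-extremum contour and are checked.
#'
#' Interior extrema other than the pinned ones, the per-segment duration
#' split, and (when `curvature_frac > 0`) a random within-segment
#' curvature are drawn from the current RNG stream (wrap the call in a
#' seeded context for reproducibility). Curvature magnitudes stay strictly
#' below the segment's frequency change, so every segment remains monotone
#' and all seven target parameters are still attained exactly; the
#' curvature only diversifies contour shape.
#'
#' @param identity Whistle-type label.
#' @param min_freq,max_freq,start_freq,end_freq Target frequencies in Hz;
#'   must satisfy `min_freq <= start_freq, end_freq <= max_freq`.
#' @param duration Target duration of the full unit in seconds (including
#'   inter-loop gaps).
#' @param n_inflections Target inflection count per loop.
#' @param n_loops,inter_loop_gap Passed to [contour_prototype()].
#' @param curvature_frac Maximum within-segment curvature as a fraction
#'   (< 1) of the segment's frequency change; 0 gives piecewise-linear
#'   contours.
#' @return A [contour_prototype()] whose [prototype_features()] equal the
#'   targets (total inflections are `n_loops * n_inflections`).
#' @export
make_prototype_from_features <- function(identity, min_freq, max_freq,
                                         start_freq, end_freq, duration,
                                         n_inflections, n_loops = 1L,
                                         inter_loop_gap = 0.15,
                                         curvature_frac = 0) {
  if (min_freq >= max_freq) stop("min_freq must be < max_freq")
  if (start_freq < min_freq || start_freq > max_freq ||
      end_freq < min_freq || end_freq > max_freq)
    stop("start/end frequencies must lie within [min_freq, max_freq]")
  n_loops <- as.integer(n_loops)
  loop_dur <- (duration - (n_loops - 1L) * inter_loop_gap) / n_loops
  if (loop_dur <= 0) stop("duration too short for the requested loop count")
  k <- as.integer(n_inflections)
  rng <- max_freq - min_freq
  if (k == 0L) {
    if (!isTRUE(all.equal(sort(c(start_freq, end_freq)),
                          c(min_freq, max_freq))))
      stop("a monotone contour (0 inflections) requires start/end to be ",
           "the min and max frequencies")
    verts <- c(start_freq, end_freq)
  } else if (k == 1L) {
    lo_se <- min(start_freq, end_freq); hi_se <- max(start_freq, end_freq)
    if (isTRUE(all.equal(lo_se, min_freq)) && max_freq > hi_se) {
      verts <- c(start_freq, max_freq, end_freq)
    } else if (isTRUE(all.equal(hi_se, max_freq)) && min_freq < lo_se) {
      verts <- c(start_freq, min_freq, end_freq)
    } else {
      stop("a single-extremum contour requires min or max to coincide ",
           "with the start/end frequencies")
    }
  } else {
    if (start_freq <= min_freq || start_freq >= max_freq ||
        end_freq <= min_freq || end_freq >= max_freq)
      stop("with >= 2 inflections the start/end frequencies must be ",
           "strictly inside (min_freq, max_freq)")
    n_hi <- ceiling(k / 2); n_lo <- floor(k / 2)
    # Highs near the ceiling, lows near the floor, so that any high exceeds
    # start/end and any low undercuts them: alternation holds by level.
    hi_band_lo <- max(start_freq, end_freq) + 1e-9
    hi_margin <- min(0.2 * rng, (max_freq - hi_band_lo) * 0.9)
    lo_band_hi <- min(start_freq, end_freq) - 1e-9
    lo_margin <- min(0.2 * rng, (lo_band_hi - min_freq) * 0.9)
    his <- max_freq - stats::runif(n_hi, 0, max(hi_margin, 0))
    los <- min_freq + stats::runif(n_lo, 0, max(lo_margin, 0))
    his[sample.int(n_hi, 1L)] <- max_freq
    los[sample.int(n_lo, 1L)] <- min_freq
    verts <- numeric(k + 2L)
    verts[1L] <- start_freq
    verts[k + 2L] <- end_freq
    verts[1L + seq_len(k)] <- as.vector(rbind(
      c(his, rep(NA, max(0, n_lo - n_hi + 1L)))[seq_len(n_hi)],
      c(los, NA)[seq_len(n_hi)]))[seq_len(k)]
  }
  n_seg <- length(verts) - 1L
  w <- stats::runif(n_seg, 0.6, 1.4)
  durs <- loop_dur * w / sum(w)
  dfreq <- verts[-1L] - verts[-length(verts)]
  curv <- if (curvature_frac > 0)
    stats::runif(n_seg, -curvature_frac, curvature_frac) * dfreq
  else rep(0, n_seg)
  contour_prototype(
    identity,
    data.frame(duration = durs, f0 = verts[-length(verts)],
               f1 = verts[-1L], curvature = curv),
    n_loops = n_loops, inter_loop_gap = inter_loop_gap)
}

#' Perturb a prototype (within-identity contour variation)
#'
#' Applies the generator's within-identity emission noise to a prototype:
#' a shared frequency offset, independent per-vertex frequency noise, and a
#' lognormal duration scaling. With all jitter parameters at zero the
#' prototype is returned unchanged, so noise-free studies carry exact
#' ground truth. Draws from the current RNG stream.
#'
#' @param proto A [contour_prototype()].
#' @param jitter A [contour_jitter()] specification.
#' @return A perturbed [contour_prototype()].
#' @export
perturb_prototype <- function(proto, jitter = contour_jitter()) {
  stopifnot(inherits(proto, "contour_prototype"))
  if (jitter$freq_offset_sd == 0 && jitter$vertex_sd == 0 &&
      jitter$duration_cv == 0) return(proto)
  seg <- proto$segments
  n_seg <- nrow(seg)
  verts <- c(seg$f0, seg$f1[n_seg])
  offset <- stats::rnorm(1L, 0, jitter$freq_offset_sd)
  verts <- verts + offset + stats::rnorm(length(verts), 0, jitter$vertex_sd)
  verts <- pmax(verts, 100)  # keep frequencies positive
  scale <- exp(stats::rnorm(1L, 0, jitter$duration_cv))
  seg$f0 <- verts[-length(verts)]
  seg$f1 <- verts[-1L]
  seg$duration <- seg$duration * scale
  contour_prototype(proto$identity, seg, proto$n_loops, proto$inter_loop_gap)
}

#' Within-identity contour jitter specification
#'
#' @param freq_offset_sd SD (Hz) of a whole-contour frequency offset shared
#'   by all vertices of one emission.
#' @param vertex_sd SD (Hz) of independent per-vertex frequency noise.
#' @param duration_cv Coefficient of variation of a lognormal duration
#'   scaling.
#' @return A list of class `contour_jitter`.
#' @export
contour_jitter <- function(freq_offset_sd = 0, vertex_sd = 0,
                           duration_cv = 0) {
  stopifnot(freq_offset_sd >= 0, vertex_sd >= 0, duration_cv >= 0)
  structure(list(freq_offset_sd = freq_offset_sd, vertex_sd = vertex_sd,
                 duration_cv = duration_cv), class = "contour_jitter")
}
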