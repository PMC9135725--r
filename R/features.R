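#' Count inflection points of a frequency contour
#'
#' An inflection point is a change of sign in the slope of the frequency
#' trajectory. The contour is first smoothed with a centered moving
#' average (ridge quantization otherwise creates spurious sign flips),
#' zero-slope runs are collapsed, and the sign changes of the first
#' differences are counted. The count is invariant to a uniform frequency
#' offset.
#'
#' @param t,f Numeric vectors: sample times (s) and frequencies (Hz); at
#'   least three samples.
#' @param smooth_window Moving-average window in samples (odd; 1 disables
#'   smoothing).
#' @return Integer inflection count.
#' @export
count_inflections <- function(t, f, smooth_window = 5L) {
  if (length(f) < 3L) stop("at least three contour samples are required")
  fs <- moving_average(f, smooth_window)
  d <- diff(fs)
  d <- d[d != 0]
  if (length(d) < 2L) return(0L)
  as.integer(sum(diff(sign(d)) != 0))
}

#' Measure the seven acoustic parameters of a whistle unit
#'
#' For the whole single- or multi-loop unit: minimum and maximum frequency
#' are extrema over all member loops; start and end frequency are the
#' first and last contour samples; frequency range is their difference
#' (max - min); duration runs from unit start to unit end, inter-loop gaps
#' included; inflection points are counted per member loop (smoothed slope
#' sign changes) and summed, so the silent gaps between loops do not
#' contribute.
#'
#' @param unit An `sw_unit` from [merge_loops()] (or a single
#'   `sw_contour`, treated as a one-loop unit).
#' @param smooth_window Passed to [count_inflections()].
#' @return One-row data frame with the seven parameters.
#' @export
measure_features <- function(unit, smooth_window = 5L) {
  if (inherits(unit, "sw_contour"))
    unit <- list(session_id = attr(unit, "session_id") %||% "S1",
                 members = list(unit), t_start = unit$t[1L],
                 t_end = unit$t[length(unit$t)], n_loops = 1L)
  n_samples <- vapply(unit$members, function(m) length(m$t), integer(1L))
  if (sum(n_samples) < 2L)
    stop("degenerate unit: fewer than two contour samples")
  f_all <- unlist(lapply(unit$members, function(m) m$f))
  first <- unit$members[[1L]]
  last <- unit$members[[length(unit$members)]]
  infl <- sum(vapply(unit$members, function(m) {
    if (length(m$f) < 3L) return(0L)
    count_inflections(m$t, m$f, smooth_window)
  }, integer(1L)))
  data.frame(
    min_freq = min(f_all),
    max_freq = max(f_all),
    start_freq = first$f[1L],
    end_freq = last$f[length(last$f)],
    freq_range = max(f_all) - min(f_all),
    n_inflections = infl,
    duration = unit$t_end - unit$t_start)
}

#' Build the signature-whistle feature table
#'
#' One row per signature-whistle unit (the analysis table the statistics
#' stage consumes): SW-ID, site, session and the seven acoustic
#' parameters. Units not assigned to a signature whistle are skipped.
#'
#' @param catalog A classified [classify_signature()] catalogue.
#' @param session_sites Optional named character vector mapping session id
#'   to site code (stored in the `site` column; `NA` otherwise).
#' @param smooth_window Passed to [measure_features()].
#' @return Data frame: `sw_id`, `site`, `session_id`, plus the seven
#'   parameters.
#' @export
feature_table <- function(catalog, session_sites = NULL,
                          smooth_window = 5L) {
  stopifnot(inherits(catalog, "sw_catalog"))
  a <- catalog$assignment
  keep <- which(!is.na(a$sw_id))
  if (!length(keep)) {
    out <- data.frame(sw_id = character(), site = character(),
                      session_id = character())
    for (nm in feature_names()) out[[nm]] <- numeric()
    return(out)
  }
  rows <- lapply(keep, function(i) {
    fv <- measure_features(catalog$units[[a$unit_id[i]]], smooth_window)
    ss <- a$session_id[i]
    cbind(data.frame(sw_id = a$sw_id[i],
                     site = if (is.null(session_sites)) NA_character_
                            else unname(session_sites[ss]),
                     session_id = ss),
          fv)
  })
  do.call(rbind, rows)
}
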