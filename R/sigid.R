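#' Contour-matching parameters
#'
#' Quantitative surrogate for the visual contour comparison used when
#' cataloguing whistle types: contours are resampled to a fixed number of
#' points on normalized time, z-normalized in frequency, and compared by
#' root-mean-square difference. Two contours match when their distance is
#' at most `threshold`. The default threshold is calibrated on the
#' synthetic generator so that same-prototype emissions under realistic
#' contour jitter match while different prototypes do not.
#'
#' @param resample_n Number of resampling points (>= 8).
#' @param metric Distance metric name; `"rms"` is the built-in metric, and
#'   a function `(a, b) -> distance` on resampled signature vectors may be
#'   supplied for pluggable alternatives (e.g. dynamic time warping).
#' @param threshold Match threshold (dimensionless, > 0).
#' @return A list of class `match_params`.
#' @export
match_params <- function(resample_n = 64L, metric = "rms",
                         threshold = 0.25) {
  resample_n <- as.integer(resample_n)
  if (resample_n < 8L) stop("resample_n must be >= 8")
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(resample_n = resample_n, metric = metric,
                 threshold = threshold), class = "match_params")
}

# Shape signature of a contour: resample to n points on normalized time,
# then z-normalize the frequencies (population SD). A constant contour is
# centered only.
contour_signature <- function(contour, params = match_params()) {
  t <- contour$t; f <- contour$f
  if (length(t) < 2L) stop("contour needs at least two samples")
  u <- (t - t[1L]) / (t[length(t)] - t[1L])
  fs <- stats::approx(u, f, xout = seq(0, 1, length.out = params$resample_n),
                      ties = "ordered")$y
  mu <- mean(fs)
  sdev <- sqrt(mean((fs - mu)^2))
  if (sdev < 1e-9) return(fs - mu)
  (fs - mu) / sdev
}

#' Shape distance between two whistle contours
#'
#' Symmetric, non-negative, invariant to uniform time shift and (through
#' the z-normalization) to uniform frequency offset and scale; zero exactly
#' when the two contours coincide after resampling and normalization.
#'
#' @param a,b `sw_contour` objects (or any list with `t` and `f`).
#' @param params [match_params()].
#' @return A non-negative scalar.
#' @export
contour_distance <- function(a, b, params = match_params()) {
  sa <- contour_signature(a, params)
  sb <- contour_signature(b, params)
  if (is.function(params$metric)) return(params$metric(sa, sb))
  sqrt(mean((sa - sb)^2))
}

#' Merge whistle loops into analysis units
#'
#' Signature whistles are often produced in loops separated by silent
#' intervals of less than 250 ms. The unit of analysis is the whole single-
#' or multi-loop whistle: consecutive contours from the same session whose
#' end-to-start gap is strictly below `gap_threshold` are merged into one
#' unit. Merging is idempotent and independent of input order (contours are
#' sorted by start time within session). Contours overlapping in time are
#' merged with a warning.
#'
#' @param contours List of `sw_contour` objects (each with a `session_id`
#'   attribute, defaulting to `"S1"`).
#' @param gap_threshold Loop-merging threshold in seconds; the boundary is
#'   exclusive (a gap of exactly 0.250 s separates two units).
#' @return A list of `sw_unit` objects: `session_id`, `members` (the loop
#'   contours, ordered), `t_start`, `t_end`, `n_loops`.
#' @export
merge_loops <- function(contours, gap_threshold = 0.250) {
  if (!length(contours)) return(list())
  sess <- vapply(contours, function(ct)
    as.character(attr(ct, "session_id") %||% "S1"), character(1L))
  starts <- vapply(contours, function(ct) ct$t[1L], numeric(1L))
  units <- list()
  for (ss in unique(sess)) {
    idx <- which(sess == ss)
    idx <- idx[order(starts[idx])]
    cur <- NULL
    flush <- function(cur) {
      structure(list(session_id = ss, members = cur$members,
                     t_start = cur$t_start, t_end = cur$t_end,
                     n_loops = length(cur$members)),
                class = "sw_unit")
    }
    for (i in idx) {
      ct <- contours[[i]]
      t0 <- ct$t[1L]; t1 <- ct$t[length(ct$t)]
      if (is.null(cur)) {
        cur <- list(members = list(ct), t_start = t0, t_end = t1)
      } else {
        gap <- t0 - cur$t_end
        if (gap < 0)
          warning("overlapping contours in session ", ss,
                  " merged into one unit")
        if (gap < gap_threshold) {
          cur$members <- c(cur$members, list(ct))
          cur$t_end <- max(cur$t_end, t1)
        } else {
          units[[length(units) + 1L]] <- flush(cur)
          cur <- list(members = list(ct), t_start = t0, t_end = t1)
        }
      }
    }
    units[[length(units) + 1L]] <- flush(cur)
  }
  units
}

# Signature of a unit: member loops concatenated on their real time axis
# (inter-loop gaps included), then resampled/normalized as one contour.
unit_signature <- function(unit, params = match_params()) {
  t <- unlist(lapply(unit$members, function(m) m$t))
  f <- unlist(lapply(unit$members, function(m) m$f))
  o <- order(t)
  contour_signature(list(t = t[o], f = f[o]), params)
}

#' Build the repeated-element whistle-type catalogue
#'
#' Groups whistle units into contour types by shape matching and applies
#' the repeated-element rule: a type is a REWT when, in at least one
#' session, two of its units occur with an end-to-start gap inside the
#' closed interval \[0.25, 10\] s; all other types are variant "other
#' whistles" (OW). Cataloguing is two-pass, mirroring a second inspection
#' of the recordings: a first sequential pass creates type entries, then
#' every unit is re-matched against the finished catalogue (nearest
#' prototype by distance, ties broken by earliest-created entry).
#'
#' @param units List of `sw_unit` from [merge_loops()].
#' @param params [match_params()].
#' @return An object of class `sw_catalog`: `entries` (one row per type:
#'   `label`, `status` REWT/OW, `sw_id`, `n_units`, `sessions`),
#'   `prototypes` (signature vectors), `assignment` (one row per unit:
#'   `unit_id`, `session_id`, `t_start`, `t_end`, `n_loops`, `label`,
#'   `distance`), and `params`.
#' @export
build_rewt_catalog <- function(units, params = match_params()) {
  if (!length(units)) stop("no whistle units to catalogue")
  sigs <- lapply(units, unit_signature, params = params)
  dist_fun <- if (is.function(params$metric)) params$metric
              else function(a, b) sqrt(mean((a - b)^2))
  # pass 1: sequential catalogue construction
  proto <- list()
  for (i in seq_along(units)) {
    d <- if (length(proto))
      vapply(proto, dist_fun, numeric(1L), b = sigs[[i]]) else numeric()
    if (!length(d) || min(d) > params$threshold)
      proto[[length(proto) + 1L]] <- sigs[[i]]
  }
  # pass 2: re-match every unit against the finished catalogue
  lab <- integer(length(units)); dmin <- numeric(length(units))
  for (i in seq_along(units)) {
    d <- vapply(proto, dist_fun, numeric(1L), b = sigs[[i]])
    lab[i] <- which.min(d)          # ties -> earliest entry
    dmin[i] <- d[lab[i]]
  }
  # label types in order of first occurrence
  first <- match(sort(unique(lab)), lab)
  ord <- order(first)
  relab <- match(lab, sort(unique(lab))[ord])
  labels <- sprintf("R%03d", relab)
  assignment <- data.frame(
    unit_id = seq_along(units),
    session_id = vapply(units, function(u) u$session_id, character(1L)),
    t_start = vapply(units, function(u) u$t_start, numeric(1L)),
    t_end = vapply(units, function(u) u$t_end, numeric(1L)),
    n_loops = vapply(units, function(u) u$n_loops, integer(1L)),
    label = labels, distance = dmin)
  entries <- do.call(rbind, lapply(sort(unique(labels)), function(lb) {
    a <- assignment[assignment$label == lb, ]
    data.frame(label = lb, status = if (is_rewt(a)) "REWT" else "OW",
               sw_id = NA_character_, n_units = nrow(a),
               sessions = paste(sort(unique(a$session_id)),
                                collapse = ";"))
  }))
  structure(list(entries = entries,
                 prototypes = stats::setNames(
                   proto[sort(unique(lab))[ord]], sort(unique(labels))),
                 assignment = assignment, units = units, params = params),
            class = "sw_catalog")
}

# REWT rule on one type's assignment rows: some session holds a pair of
# units with end-to-start gap in [0.25, 10] s.
is_rewt <- function(a, window = c(0.25, 10)) {
  for (ss in unique(a$session_id)) {
    s <- a[a$session_id == ss, ]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) for (j in seq(i + 1L, nrow(s))) {
      g <- max(s$t_start[i], s$t_start[j]) - min(s$t_end[i], s$t_end[j])
      if (g >= window[1L] && g <= window[2L]) return(TRUE)
    }
  }
  FALSE
}

#' Apply the signature-whistle bout criterion
#'
#' Promotes catalogue entries to signature whistles under the SIGID rule:
#' an entry is a signature whistle if, in at least one recorded session, it
#' has a minimum of four units and at least 75% of those units occur
#' within 1-10 s (end-to-start, closed interval) of at least one other
#' unit of the same type. The 75% clause is compared with `>=`, so 3 of 4
#' qualifies. Each signature whistle receives a unique SW-ID, inherited by
#' all units of the same contour type study-wide.
#'
#' @param catalog An [build_rewt_catalog()] catalogue.
#' @param min_units Minimum stereotyped contours per session (default 4).
#' @param gap_window Closed gap window in seconds (default \[1, 10\]).
#' @param min_fraction Minimum qualifying fraction (default 0.75).
#' @return The catalogue with `status` upgraded to `"SW"` where the rule
#'   holds, `sw_id` filled in, and an `sw_id` column on the assignment.
#' @export
classify_signature <- function(catalog, min_units = 4L,
                               gap_window = c(1, 10),
                               min_fraction = 0.75) {
  stopifnot(inherits(catalog, "sw_catalog"))
  entries <- catalog$entries
  assignment <- catalog$assignment
  is_sw <- logical(nrow(entries))
  for (k in seq_len(nrow(entries))) {
    if (entries$status[k] != "REWT") next
    a <- assignment[assignment$label == entries$label[k], ]
    for (ss in unique(a$session_id)) {
      s <- a[a$session_id == ss, ]
      n <- nrow(s)
      if (n < min_units) next
      nearest <- vapply(seq_len(n), function(i) {
        g <- vapply(seq_len(n), function(j) {
          if (i == j) return(Inf)
          max(s$t_start[i], s$t_start[j]) - min(s$t_end[i], s$t_end[j])
        }, numeric(1L))
        min(g)
      }, numeric(1L))
      frac <- mean(nearest >= gap_window[1L] & nearest <= gap_window[2L])
      if (frac >= min_fraction) { is_sw[k] <- TRUE; break }
    }
  }
  sw_labels <- entries$label[is_sw]
  sw_ids <- stats::setNames(sprintf("SW%03d", seq_along(sw_labels)),
                            sw_labels)
  entries$status[is_sw] <- "SW"
  entries$sw_id[is_sw] <- sw_ids[entries$label[is_sw]]
  assignment$sw_id <- unname(sw_ids[assignment$label])
  catalog$entries <- entries
  catalog$assignment <- assignment
  catalog
}

#' @export
print.sw_catalog <- function(x, ...) {
  st <- table(factor(x$entries$status, levels = c("SW", "REWT", "OW")))
  cat("Whistle-type catalogue:", nrow(x$entries), "types over",
      nrow(x$assignment), "units\n")
  cat(sprintf("  SW: %d  REWT (non-SW): %d  OW: %d\n",
              st[["SW"]], st[["REWT"]], st[["OW"]]))
  invisible(x)
}

#' Write catalogue outputs
#'
#' @param catalog An `sw_catalog`.
#' @param json_path Optional path for the catalogue JSON (entries with
#'   status, SW-ID and supporting units).
#' @param csv_path Optional path for the per-unit assignment CSV.
#' @return The assignment data frame, invisibly.
#' @export
write_catalog <- function(catalog, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(catalog, "sw_catalog"))
  if (!is.null(json_path)) {
    ent <- catalog$entries
    ent$units <- vapply(ent$label, function(lb)
      paste(catalog$assignment$unit_id[catalog$assignment$label == lb],
            collapse = ";"), character(1L))
    jsonlite::write_json(ent, json_path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(catalog$assignment, csv_path, row.names = FALSE)
  invisible(catalog$assignment)
}
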