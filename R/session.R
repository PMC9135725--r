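#' Sample a recording session from a synthetic study
#'
#' Builds a timed emission schedule for one recording session at one site,
#' together with the emitted contours (one traced contour per loop). Each
#' identity emits one bout; bouts are placed sequentially with inter-bout
#' gaps larger than the 10 s signature window, so bout structure within an
#' identity is fully controlled and whistles from different identities never
#' overlap in time:
#'
#' * `SW`-compliant identities emit at least four whistle units with
#'   end-to-start gaps drawn inside the 1-10 s signature window, so every
#'   unit's nearest same-type gap qualifies.
#' * `REWT` identities emit two or three units with gaps inside the
#'   0.25-10 s repeated-element window (repeated, but fewer than four
#'   units, hence not signature whistles).
#' * `OW` identities and session-level variant whistles emit a single unit
#'   each (variants carry unique throwaway identities).
#' * A non-compliant specification (`compliant = FALSE` with `n >= 4`)
#'   spreads the units more than 10 s apart, violating both the signature
#'   and the repeated-element gap clause.
#'
#' @param study A [make_repertoire()] study.
#' @param site Site code of the session (must exist in the study).
#' @param session_id Session identifier.
#' @param bout_spec Optional data frame (`identity`, `n`, `compliant`)
#'   overriding the default per-class bout behaviour.
#' @param duration Session duration in seconds. If the scheduled bouts do
#'   not fit, generation fails with an error.
#' @param n_variants Number of additional one-off variant whistles.
#' @param dt Contour sampling step, seconds.
#' @param seed Integer seed.
#' @return A list of class `sw_session`: `events` (one row per whistle
#'   unit: `session_id`, `emission_id`, `identity`, `class`, `t_start`,
#'   `t_end`, `n_loops`) and `contours` (list of `sw_contour`, one per
#'   loop, each tagged with its `emission_id`).
#' @export
sample_session <- function(study, site, session_id = "S1",
                           bout_spec = NULL, duration = 900,
                           n_variants = 2L, dt = 0.01, seed = NULL) {
  stopifnot(inherits(study, "synthetic_study"), duration > 0)
  if (!site %in% study$sites$site) stop("unknown site: ", site)
  ids <- study$identities[study$identities$site == site, ]
  with_seed(seed, {
    if (is.null(bout_spec)) {
      bout_spec <- data.frame(
        identity = ids$identity,
        n = ifelse(ids$class == "SW", sample(4:7, nrow(ids), replace = TRUE),
            ifelse(ids$class == "REWT",
                   sample(2:3, nrow(ids), replace = TRUE), 1L)),
        compliant = ids$class %in% c("SW", "REWT"))
      bout_spec$window <- ifelse(ids$class == "REWT", "rewt", "sw")
    } else {
      bout_spec <- as.data.frame(bout_spec)
      stopifnot(all(c("identity", "n", "compliant") %in% names(bout_spec)))
      if (is.null(bout_spec$window)) bout_spec$window <- "sw"
      bad <- setdiff(bout_spec$identity, study$identities$identity)
      if (length(bad))
        stop("bout_spec names unknown identities: ",
             paste(bad, collapse = ", "))
    }
    jitter <- study$effects$jitter
    # variant whistles: unique throwaway identities, drawn like prototypes
    variant_protos <- list()
    if (n_variants > 0L) {
      sigs <- lapply(study$prototypes, function(p)
        contour_signature(prototype_contour(p, dt = 0.01)[[1L]],
                          study$match))
      for (v in seq_len(n_variants)) {
        vid <- paste0(session_id, "_VAR", v)
        vp <- draw_prototype(vid, study$band,
                             site_shift(study$effects,
                                        study$sites[study$sites$site == site, ]),
                             study$effects$id_sd, sigs,
                             study$min_separation, study$match)
        variant_protos[[vid]] <- vp
        sigs[[vid]] <- contour_signature(
          prototype_contour(vp, dt = 0.01)[[1L]], study$match)
      }
    }
    # build one bout per identity, then place bouts on the timeline
    bouts <- list()
    for (bi in seq_len(nrow(bout_spec))) {
      sp <- bout_spec[bi, ]
      n <- as.integer(sp$n)
      gaps <- if (n <= 1L) numeric() else if (isTRUE(sp$compliant)) {
        if (identical(sp$window, "rewt")) stats::runif(n - 1L, 0.4, 9.0)
        else stats::runif(n - 1L, 2.0, 9.0)
      } else stats::runif(n - 1L, 12, 20)
      bouts[[length(bouts) + 1L]] <-
        list(identity = sp$identity, gaps = gaps, n = n)
    }
    for (vid in names(variant_protos))
      bouts[[length(bouts) + 1L]] <- list(identity = vid, gaps = numeric(),
                                          n = 1L)
    bouts <- bouts[sample.int(length(bouts))]
    protos <- c(study$prototypes, variant_protos)
    events <- list(); contours <- list()
    cursor <- stats::runif(1L, 1, 4)
    emission_id <- 0L
    for (b in bouts) {
      proto <- protos[[b$identity]]
      for (e in seq_len(b$n)) {
        emission_id <- emission_id + 1L
        realized <- perturb_prototype(proto, jitter)
        loops <- prototype_contour(realized, t0 = cursor, dt = dt)
        t_end <- max(loops[[length(loops)]]$t)
        cls <- study$identities$class[
          study$identities$identity == b$identity]
        if (!length(cls)) cls <- "OW"  # session variants
        events[[emission_id]] <- data.frame(
          session_id = session_id, emission_id = emission_id,
          identity = b$identity, class = cls, t_start = cursor,
          t_end = t_end, n_loops = realized$n_loops)
        for (lp in loops) {
          attr(lp, "emission_id") <- emission_id
          attr(lp, "session_id") <- session_id
          contours[[length(contours) + 1L]] <- lp
        }
        if (e < b$n) cursor <- t_end + b$gaps[e]
      }
      cursor <- max(cursor, t_end) + stats::runif(1L, 12, 20)
    }
    events <- do.call(rbind, events)
    if (max(events$t_end) > duration)
      stop("session too short: scheduled emissions run to ",
           round(max(events$t_end), 1), " s but duration is ", duration,
           " s")
    structure(list(events = events, contours = contours,
                   session_id = session_id, site = site),
              class = "sw_session")
  })
}

#' Derive ground-truth SIGID labels from an emission schedule
#'
#' Independent rule checker used to validate generator truth: applies the
#' repeated-element and signature rules directly to the scheduled whistle
#' units of each identity within each session. An identity's units in a
#' session are labelled `SW` if there are at least four of them and at
#' least 75% have a nearest same-identity end-to-start gap within 1-10 s;
#' otherwise `REWT` if some pair of units has a gap within 0.25-10 s;
#' otherwise `OW`.
#'
#' @param events Event table as produced by [sample_session()].
#' @return The event table with a `truth` column.
#' @export
sigid_truth <- function(events) {
  events$truth <- "OW"
  for (ss in unique(events$session_id)) {
    in_s <- events$session_id == ss
    for (id in unique(events$identity[in_s])) {
      sel <- in_s & events$identity == id
      st <- events$t_start[sel]; en <- events$t_end[sel]
      n <- sum(sel)
      if (n < 2L) next
      gap <- function(i, j)
        max(st[i], st[j]) - min(en[i], en[j])
      pair_gaps <- outer(seq_len(n), seq_len(n),
                         Vectorize(function(i, j)
                           if (i == j) NA_real_ else gap(i, j)))
      rewt <- any(pair_gaps >= 0.25 & pair_gaps <= 10, na.rm = TRUE)
      label <- "OW"
      if (rewt) label <- "REWT"
      if (n >= 4L) {
        nearest <- apply(pair_gaps, 1L, min, na.rm = TRUE)
        if (mean(nearest >= 1 & nearest <= 10) >= 0.75) label <- "SW"
      }
      events$truth[sel] <- label
    }
  }
  events
}

#' Write the ground-truth emission table of one or more sessions
#'
#' @param sessions A single `sw_session` or list of them.
#' @param path CSV output path (`session_id`, `identity`, `t_start`,
#'   `t_end`, `label`).
#' @return The written data frame, invisibly.
#' @export
write_truth_csv <- function(sessions, path) {
  if (inherits(sessions, "sw_session")) sessions <- list(sessions)
  ev <- do.call(rbind, lapply(sessions, function(s) s$events))
  out <- data.frame(session_id = ev$session_id, identity = ev$identity,
                    t_start = ev$t_start, t_end = ev$t_end,
                    label = ev$class)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
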