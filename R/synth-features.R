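#' Simulate a measured feature table from a study
#'
#' Emits `obs_per_id` jittered whistles per identity and measures the
#' seven parameters of each emission, producing the per-contour analysis
#' table directly (the classification stages, which have their own ground
#' truth, are bypassed). This is the generator used for power and
#' false-positive studies of the variability analysis: identity-level
#' parameter draws provide the random-intercept structure and the emission
#' jitter provides the residual.
#'
#' @param study A [make_repertoire()] study.
#' @param obs_per_id Number of emissions measured per identity. May be a
#'   single value or one value per identity.
#' @param classes Identity classes to include (default signature whistles
#'   only).
#' @param dt Contour sampling step, s.
#' @param seed Integer seed.
#' @return Feature table: `sw_id` (the identity), `site`, `session_id`
#'   (synthetic, one per identity), and the seven parameters, one row per
#'   emission.
#' @export
simulate_feature_study <- function(study, obs_per_id = 12L,
                                   classes = "SW", dt = 0.01,
                                   seed = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  ids <- study$identities[study$identities$class %in% classes, ]
  n_obs <- rep_len(obs_per_id, nrow(ids))
  jitter <- study$effects$jitter
  with_seed(seed, {
    rows <- vector("list", sum(n_obs))
    k <- 0L
    for (i in seq_len(nrow(ids))) {
      proto <- study$prototypes[[ids$identity[i]]]
      for (r in seq_len(n_obs[i])) {
        k <- k + 1L
        realized <- perturb_prototype(proto, jitter)
        unit <- merge_loops(prototype_contour(realized, dt = dt))[[1L]]
        rows[[k]] <- cbind(
          data.frame(sw_id = ids$identity[i], site = ids$site[i],
                     session_id = paste0(ids$identity[i], "_sim")),
          measure_features(unit))
      }
    }
    do.call(rbind, rows)
  })
}
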