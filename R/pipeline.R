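#' Pipeline run configuration
#'
#' Single configuration object for end-to-end runs. Every classification
#' threshold of the method chain appears as a named, defaulted field so
#' sensitivity analyses are one-line changes: the 250 ms loop-merging gap,
#' the 0.25-10 s repeated-element window, the 1-10 s signature window with
#' its four-unit minimum and 75% clause, the fourth-root flag of the
#' Bray-Curtis stage and the Kaiser retention flag of the PCA stage.
#' The configuration round-trips through JSON unchanged.
#'
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "extract", "classify", "features", "stats")`.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param sites,sw_per_site,n_rewt_per_site,n_ow_per_site,effects Generator
#'   settings (see [make_repertoire()]).
#' @param sessions_per_site Recording sessions simulated per site.
#' @param session_duration Session length in seconds.
#' @param n_variants Variant whistles per session.
#' @param audio Render and re-extract audio (otherwise the event-level
#'   contours feed the classifier directly).
#' @param sample_rate,snr_db Audio rendering settings.
#' @param extraction [extraction_params()].
#' @param match [match_params()].
#' @param loop_gap Loop-merging threshold, s.
#' @param rewt_window,sw_window REWT and signature gap windows, s.
#' @param sw_min_units,sw_min_fraction Signature rule: minimum units and
#'   minimum qualifying fraction.
#' @param fourth_root,kaiser,n_perm,n_restarts,outlier_z Statistics-stage
#'   settings.
#' @param outdir Output directory (`NULL` for in-memory only).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "classify", "features",
                                       "stats"),
                            seed = 1L, sites = mediterranean_sites(),
                            sw_per_site = 3L, n_rewt_per_site = 1L,
                            n_ow_per_site = 1L, effects = effect_config(),
                            sessions_per_site = 2L,
                            session_duration = 1800,
                            n_variants = 2L, audio = FALSE,
                            sample_rate = 96000, snr_db = 30,
                            extraction = extraction_params(),
                            match = match_params(), loop_gap = 0.250,
                            rewt_window = c(0.25, 10),
                            sw_window = c(1, 10), sw_min_units = 4L,
                            sw_min_fraction = 0.75, fourth_root = TRUE,
                            kaiser = TRUE, n_perm = 999L,
                            n_restarts = 50L, outlier_z = 3,
                            outdir = NULL) {
  known <- c("simulate", "extract", "classify", "features", "stats")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> (render + extract) -> classify -> features ->
#' stats from one configuration, with per-stage attrition logging and a
#' reproducibility manifest (configuration hash and all seeds). Later
#' stages consume the outputs of earlier ones; disabling a stage leaves
#' earlier outputs untouched, and a stage whose input is missing fails
#' with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @param features Optional pre-computed feature table (lets a stats-only
#'   run proceed without the simulation stages).
#' @return A list of class `sw_report`: study, sessions, catalogue,
#'   feature tables, similarity/ANOSIM/PCA/model/clustering results,
#'   per-site SW unit and SW-ID counts, a stage log, and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), features = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  log <- list()
  out <- list(config = config)
  seed <- as.integer(config$seed)
  study <- NULL; sessions <- NULL; contours <- NULL
  if ("simulate" %in% stages) {
    study <- make_repertoire(
      sites = config$sites, sw_per_site = config$sw_per_site,
      effects = config$effects, n_rewt_per_site = config$n_rewt_per_site,
      n_ow_per_site = config$n_ow_per_site, match = config$match,
      seed = seed)
    sessions <- list()
    k <- 0L
    for (site in config$sites$site) {
      for (r in seq_len(config$sessions_per_site)) {
        k <- k + 1L
        sessions[[k]] <- sample_session(
          study, site = site, session_id = sprintf("%s_S%02d", site, r),
          duration = config$session_duration,
          n_variants = config$n_variants, seed = seed + 1000L + k)
      }
    }
    contours <- unlist(lapply(sessions, function(s) s$contours),
                       recursive = FALSE)
    log$simulate <- list(n_identities = nrow(study$identities),
                         n_sessions = length(sessions),
                         n_contours = length(contours))
    if (config$audio) {
      if (!"extract" %in% stages)
        stop("stage 'extract' is required when audio rendering is enabled")
      contours <- list()
      for (s in sessions) {
        wav <- render_audio(s, sample_rate = config$sample_rate,
                            snr_db = config$snr_db,
                            band = config$extraction$band,
                            seed = seed + 2000L + match(s$session_id,
                              vapply(sessions, `[[`, "", "session_id")))
        cts <- extract_whistles(wav, params = config$extraction,
                                session_id = s$session_id)
        contours <- c(contours, cts)
      }
      log$extract <- list(n_kept = length(contours))
    }
  }
  session_sites <- if (!is.null(sessions))
    stats::setNames(vapply(sessions, function(s) s$site, character(1L)),
                    vapply(sessions, function(s) s$session_id,
                           character(1L)))
  catalog <- NULL
  if ("classify" %in% stages) {
    if (is.null(contours))
      stop("stage 'classify' needs contours; enable 'simulate' or supply ",
           "a feature table for a stats-only run")
    units <- merge_loops(contours, gap_threshold = config$loop_gap)
    catalog <- build_rewt_catalog(units, params = config$match)
    catalog <- classify_signature(
      catalog, min_units = config$sw_min_units,
      gap_window = config$sw_window,
      min_fraction = config$sw_min_fraction)
    st <- table(factor(catalog$entries$status,
                       levels = c("SW", "REWT", "OW")))
    log$classify <- list(n_units = length(units),
                         n_types = nrow(catalog$entries),
                         n_sw = unname(st[["SW"]]),
                         n_rewt = unname(st[["REWT"]]),
                         n_ow = unname(st[["OW"]]))
  }
  if ("features" %in% stages) {
    if (is.null(catalog))
      stop("stage 'features' needs a catalogue; enable 'classify'")
    features <- feature_table(catalog, session_sites = session_sites)
    log$features <- list(n_rows = nrow(features))
  }
  out$study <- study; out$sessions <- sessions; out$catalog <- catalog
  out$features <- features
  # per-site summary: SW contour counts and distinct SW-IDs
  if (!is.null(features) && nrow(features)) {
    out$site_summary <- do.call(rbind, lapply(
      sort(unique(features$site)), function(s) {
        d <- features[features$site == s, ]
        data.frame(site = s, n_sw_units = nrow(d),
                   n_sw_ids = length(unique(d$sw_id)))
      }))
  }
  if ("stats" %in% stages) {
    if (is.null(features))
      stop("stage 'stats' needs a feature table; enable 'features' or ",
           "pass one explicitly")
    out$stats <- analyse_features(
      features, sites = config$sites, fourth_root = config$fourth_root,
      kaiser = config$kaiser, n_perm = config$n_perm,
      n_restarts = config$n_restarts, outlier_z = config$outlier_z,
      seed = seed + 5000L)
  }
  out$log <- log
  out$manifest <- list(
    config_hash = config_hash(config), seed = seed,
    stage_seeds = list(simulate = seed, sessions = seed + 1000L,
                       audio = seed + 2000L, stats = seed + 5000L),
    package_version = as.character(utils::packageVersion("sigwhistle")))
  class(out) <- "sw_report"
  if (!is.null(config$outdir)) write_report(out, config$outdir)
  out
}

#' Statistical analysis of a feature table
#'
#' The statistics stage on its own: per-SW mean table, fourth-root
#' Bray-Curtis dissimilarity, nMDS, one-way ANOSIM per factor (site,
#' region, sea bottom, demography), robust outlier removal, correlation
#' PCA with Kaiser retention, and one Gaussian mixed model per retained
#' component and factor with SW-ID random intercepts; plus the two site
#' clusterings.
#'
#' @param features Feature table (`sw_id`, `site`, seven parameters).
#' @param sites Site table supplying the factor levels per site.
#' @param fourth_root,kaiser,n_perm,n_restarts,outlier_z,seed See
#'   [pipeline_config()].
#' @return A list with `mean_table`, `dist`, `nmds`, `anosim` (per
#'   factor), `pca`, `models` (per factor, per component), `clusterings`,
#'   `outliers_removed`.
#' @export
analyse_features <- function(features, sites = mediterranean_sites(),
                             fourth_root = TRUE, kaiser = TRUE,
                             n_perm = 999L, n_restarts = 50L,
                             outlier_z = 3, seed = NULL) {
  stopifnot(nrow(features) > 0)
  factors <- c("site", "region", "sea_bottom", "demography")
  site_fac <- sites[, c("site", "region", "sea_bottom", "demography")]
  features <- merge(features, site_fac, by = "site", sort = FALSE)
  mt <- mean_feature_table(features)
  mt <- merge(mt, site_fac, by = "site", sort = FALSE)
  d <- bray_curtis(mt[feature_names()], fourth_root = fourth_root)
  attr(d, "Labels") <- mt$sw_id
  nm <- nmds_ordination(d, n_restarts = n_restarts,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  anosims <- list()
  for (fc in factors) {
    g <- mt[[fc]]
    ok <- length(unique(g)) >= 2L && all(table(g) >= 2L)
    anosims[[fc]] <- if (ok)
      anosim_perm(d, g, n_perm = n_perm,
                  seed = if (is.null(seed)) NULL else
                    seed + 10L + match(fc, factors))
    else NULL
  }
  clean <- remove_outliers(features, z = outlier_z)
  pca <- pca_reduce(clean[feature_names()], kaiser = kaiser,
                    orient = acoustic_pca_orientation())
  scores <- as.data.frame(pca$scores[, seq_len(pca$k), drop = FALSE])
  names(scores) <- paste0("PC", seq_len(pca$k))
  model_data <- cbind(clean, scores)
  models <- list()
  for (fc in factors) {
    if (length(unique(model_data[[fc]])) < 2L) next
    models[[fc]] <- lapply(names(scores), function(pc)
      fit_glmm(model_data, pc, fc, id = "sw_id"))
    names(models[[fc]]) <- names(scores)
  }
  clusterings <- list(
    sea_bottom = cluster_sites(encode_sea_bottom(sites), "ward",
                               n_clusters = 3L, prefix = "H"),
    demography = cluster_sites(encode_demography(sites), "complete",
                               n_clusters = 4L, prefix = "P"))
  list(mean_table = mt, dist = d, nmds = nm, anosim = anosims, pca = pca,
       models = models, clusterings = clusterings,
       outliers_removed = nrow(features) - nrow(clean),
       model_data = model_data)
}

# Deterministic hash of a configuration: md5 of its canonical JSON.
# The output directory is a runtime location, not analysis content, and
# is excluded so reruns into different directories hash identically.
config_hash <- function(config) {
  plain <- config
  plain$outdir <- NULL
  plain$effects <- unclass(plain$effects)
  plain$effects$jitter <- unclass(plain$effects$jitter)
  plain$extraction <- unclass(plain$extraction)
  plain$match <- unclass(plain$match)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain[order(names(plain))], tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write pipeline outputs to a directory
#'
#' Writes the standard artefacts of a run: truth and contour CSVs,
#' catalogue JSON and assignment CSV, feature and mean-feature CSVs,
#' distance matrix CSV, ordination coordinates CSV, ANOSIM/PCA results
#' JSON, model tables CSV (Value, SE, DF, t-value, p-value plus random and
#' residual SDs per model), the run report JSON (timestamp-free, so reruns
#' are byte-identical) and the manifest.
#'
#' @param report An `sw_report` from [run_pipeline()].
#' @param outdir Output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)
  if (!is.null(report$sessions))
    write_truth_csv(report$sessions, pth("truth.csv"))
  if (!is.null(report$catalog))
    write_catalog(report$catalog, pth("catalog.json"),
                  pth("assignments.csv"))
  if (!is.null(report$features))
    utils::write.csv(report$features, pth("features.csv"),
                     row.names = FALSE)
  st <- report$stats
  if (!is.null(st)) {
    utils::write.csv(st$mean_table, pth("mean_features.csv"),
                     row.names = FALSE)
    m <- as.matrix(st$dist)
    rownames(m) <- colnames(m) <- attr(st$dist, "Labels")
    utils::write.csv(m, pth("distance_matrix.csv"))
    utils::write.csv(data.frame(sw_id = rownames(st$nmds$points),
                                st$nmds$points),
                     pth("nmds_coordinates.csv"), row.names = FALSE)
    res <- list(
      nmds_stress = st$nmds$stress,
      anosim = lapply(st$anosim, function(a)
        if (is.null(a)) NULL else list(R = a$statistic, p = a$p.value,
                                       n_perm = a$n_perm)),
      pca = list(k = st$pca$k,
                 variance_fraction = st$pca$variance_fraction,
                 loadings = as.data.frame(st$pca$loadings)),
      outliers_removed = st$outliers_removed)
    jsonlite::write_json(res, pth("stats.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    rows <- list()
    for (fc in names(st$models)) for (pc in names(st$models[[fc]])) {
      mm <- st$models[[fc]][[pc]]
      fx <- mm$fixed
      fx$factor <- fc; fx$component <- pc
      fx$sd_intercept <- mm$sd_intercept
      fx$sd_residual <- mm$sd_residual
      rows[[length(rows) + 1L]] <- fx
    }
    if (length(rows))
      utils::write.csv(do.call(rbind, rows), pth("model_tables.csv"),
                       row.names = FALSE)
  }
  if (!is.null(report$site_summary))
    utils::write.csv(report$site_summary, pth("site_summary.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(log = report$log, manifest = report$manifest,
                            site_summary = report$site_summary),
                       pth("report.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(outdir)
}

#' @export
print.sw_report <- function(x, ...) {
  cat("Signature-whistle pipeline report\n")
  if (!is.null(x$site_summary)) {
    cat("Per-site signature whistles:\n")
    print(x$site_summary, row.names = FALSE)
  }
  if (!is.null(x$stats)) {
    cat(sprintf("nMDS stress: %.3f; PCA: %d components (%.0f%% variance)\n",
                x$stats$nmds$stress, x$stats$pca$k,
                100 * sum(x$stats$pca$variance_fraction[
                  seq_len(x$stats$pca$k)])))
    for (fc in names(x$stats$anosim)) {
      a <- x$stats$anosim[[fc]]
      if (!is.null(a))
        cat(sprintf("  ANOSIM %-11s R = %6.3f  p = %.4g\n", fc,
                    a$statistic, a$p.value))
    }
  }
  cat("Manifest hash:", x$manifest$config_hash, "\n")
  invisible(x)
}
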