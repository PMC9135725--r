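#' Robust-z outlier removal
#'
#' Drops rows whose robust z-score (median and MAD based) exceeds `z` in
#' absolute value on any of the seven raw parameters; the removed rows are
#' attached as the `"removed"` attribute so the attrition can be logged.
#' Parameters with zero MAD (e.g. a constant inflection count) are skipped.
#'
#' @param features Feature table with the seven parameter columns.
#' @param z Robust z threshold (default 3).
#' @return The filtered table, with attribute `removed`.
#' @export
remove_outliers <- function(features, z = 3) {
  keep <- rep(TRUE, nrow(features))
  for (nm in intersect(feature_names(), names(features))) {
    x <- features[[nm]]
    s <- stats::mad(x)
    if (s == 0) next
    keep <- keep & abs(x - stats::median(x)) / s <= z
  }
  out <- features[keep, , drop = FALSE]
  attr(out, "removed") <- features[!keep, , drop = FALSE]
  out
}

#' Principal component reduction with Kaiser retention
#'
#' Correlation-matrix PCA of the (collinear) acoustic parameters, retaining
#' the components whose eigenvalue is at least 1 (Kaiser's criterion) when
#' `kaiser = TRUE`. Because eigenvector signs are arbitrary, a declared
#' orientation convention is applied: by default each retained loading
#' vector is flipped so its largest-magnitude element is positive;
#' alternatively `orient` may give, per retained component, a reference
#' variable and the desired sign of its loading (see
#' [acoustic_pca_orientation()] for the reporting orientation used for the
#' seven whistle parameters).
#'
#' @param x Numeric data frame or matrix (>= 8 rows). Non-numeric columns
#'   are dropped.
#' @param kaiser Retain only components with eigenvalue >= 1.
#' @param orient Either `"dominant"` or a list of `list(var =, sign =)`
#'   entries, one per retained component.
#' @return An object of class `sw_pca`: `loadings` (p x p, oriented),
#'   `scores` (n x p), `eigenvalues`, `variance_fraction` (sums to 1 over
#'   all components), `k` (number retained), `center`, `scale`.
#' @export
pca_reduce <- function(x, kaiser = TRUE, orient = "dominant") {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1L))])
  if (nrow(x) < 8L) stop("need at least 8 observations")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- p$sdev^2
  varfrac <- eig / sum(eig)
  k <- if (kaiser) max(1L, sum(eig >= 1)) else ncol(x)
  load <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(load))) {
    flip <- if (is.list(orient) && j <= min(k, length(orient))) {
      ref <- orient[[j]]
      sign(load[ref$var, j]) != sign(ref$sign)
    } else {
      load[which.max(abs(load[, j])), j] < 0
    }
    if (isTRUE(flip)) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = load, scores = scores, eigenvalues = eig,
                 variance_fraction = varfrac, k = k,
                 center = p$center, scale = p$scale),
            class = "sw_pca")
}

#' @export
print.sw_pca <- function(x, ...) {
  cat(sprintf("PCA: %d components retained (Kaiser), %.0f%% of variance\n",
              x$k, 100 * sum(x$variance_fraction[seq_len(x$k)])))
  print(round(x$loadings[, seq_len(x$k), drop = FALSE], 3))
  invisible(x)
}

#' Reporting orientation for the seven-parameter PCA
#'
#' The orientation convention used when reporting whistle-parameter
#' components: the first component is oriented negative on the maximum
#' frequency (so it contrasts max/end frequencies), the second positive on
#' the minimum frequency (min/start block), and the third positive on
#' duration (duration/inflections against frequency range).
#'
#' @return A list suitable for the `orient` argument of [pca_reduce()].
#' @export
acoustic_pca_orientation <- function() {
  list(list(var = "max_freq", sign = -1),
       list(var = "min_freq", sign = 1),
       list(var = "duration", sign = 1))
}

#' Simulate a parameter table with three correlated blocks
#'
#' Structural test-bed for the component reduction: draws a seven-column
#' table whose correlation structure has three orthogonal latent blocks -
#' max/end frequency, min/start frequency, and duration/inflections
#' against frequency range (the last loading negatively). Block strengths
#' are graded so the blocks emerge as the first, second and third
#' components respectively.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return Data frame with the seven parameter columns.
#' @export
simulate_feature_blocks <- function(n = 500L, seed = NULL) {
  with_seed(seed, {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)
    e <- function(s) stats::rnorm(n, 0, s)
    data.frame(
      min_freq = 7000 + 800 * (z2 + e(0.65)),
      max_freq = 15000 + 1500 * (z1 + e(0.20)),
      start_freq = 8000 + 900 * (z2 + e(0.65)),
      end_freq = 14000 + 1400 * (z1 + e(0.20)),
      freq_range = 8000 + 1200 * (-z3 + e(1.73)),
      n_inflections = 3 + 1.2 * (z3 + e(1.73)),
      duration = 0.8 + 0.3 * (z3 + e(1.73)))
  })
}

#' Gaussian mixed model with per-whistle random intercepts
#'
#' Fits a linear mixed model by REML with a single categorical fixed
#' effect and a random intercept per signature whistle (SW-ID), the model
#' used to relate component scores to region, site, sea bottom or
#' demography while accounting for repeated contours of the same whistle
#' type. Denominator degrees of freedom follow the between-within
#' (containment) convention. Residual diagnostics (normality test on the
#' within-group residuals, fitted values) are attached for graphical
#' inspection.
#'
#' @param data Data frame with the response, factor and grouping columns.
#' @param response Name of the (numeric) response column, e.g. a PC score.
#' @param factor_name Name of the categorical fixed-effect column.
#' @param id Name of the grouping column (default `"sw_id"`).
#' @return An object of class `sw_glmm`: `fixed` (per-level `Value`,
#'   `SE`, `DF`, `t_value`, `p_value`), `sd_intercept`, `sd_residual`,
#'   `term_test` (conditional F-test of the factor), `boundary` (TRUE if
#'   the random-intercept variance collapsed to the boundary),
#'   `diagnostics`, and the underlying `nlme::lme` fit.
#' @export
fit_glmm <- function(data, response, factor_name, id = "sw_id") {
  stopifnot(all(c(response, factor_name, id) %in% names(data)))
  data <- data.frame(.y = data[[response]],
                     .f = factor(data[[factor_name]]),
                     .id = factor(data[[id]]))
  if (nlevels(data$.f) < 2L) stop("factor needs at least two levels")
  fit <- tryCatch(
    nlme::lme(.y ~ .f, random = ~ 1 | .id, data = data, method = "REML"),
    error = function(e) stop("mixed model did not converge: ",
                             conditionMessage(e), call. = FALSE))
  tt <- summary(fit)$tTable
  lev <- levels(data$.f)
  fixed <- data.frame(
    effect = c("(Intercept)", lev[-1L]),
    Value = tt[, "Value"], SE = tt[, "Std.Error"], DF = tt[, "DF"],
    t_value = tt[, "t-value"], p_value = tt[, "p-value"],
    row.names = NULL)
  vc <- nlme::VarCorr(fit)
  sd_int <- as.numeric(vc["(Intercept)", "StdDev"])
  sd_res <- as.numeric(vc["Residual", "StdDev"])
  an <- stats::anova(fit)
  res <- stats::residuals(fit, type = "pearson")
  shapiro_p <- if (length(res) >= 3L && length(res) <= 5000L)
    stats::shapiro.test(res)$p.value else NA_real_
  structure(list(
    fixed = fixed, sd_intercept = sd_int, sd_residual = sd_res,
    term_test = list(F = an[".f", "F-value"], num_df = an[".f", "numDF"],
                     den_df = an[".f", "denDF"],
                     p_value = an[".f", "p-value"]),
    boundary = sd_int < 1e-3 * sd_res,
    diagnostics = list(shapiro_p = shapiro_p,
                       fitted = stats::fitted(fit),
                       residuals = res),
    response = response, factor_name = factor_name, fit = fit),
    class = "sw_glmm")
}

#' @export
print.sw_glmm <- function(x, ...) {
  cat("Gaussian mixed model:", x$response, "~", x$factor_name,
      "+ (1 |", "SW-ID)\n")
  print(transform(x$fixed, Value = round(Value, 4), SE = round(SE, 4),
                  t_value = round(t_value, 3),
                  p_value = signif(p_value, 3)))
  cat(sprintf("Random intercept SD: %.4f  Residual SD: %.4f%s\n",
              x$sd_intercept, x$sd_residual,
              if (x$boundary) "  [boundary variance]" else ""))
  cat(sprintf("Factor F-test: F(%d, %d) = %.3f, p = %.4g\n",
              x$term_test$num_df, x$term_test$den_df, x$term_test$F,
              x$term_test$p_value))
  invisible(x)
}

#' Hierarchical clustering of sites
#'
#' Agglomerative clustering of an encoded site table with Euclidean
#' distance, using Ward linkage (`"ward"`, implemented as Ward's D2 on
#' unsquared distances) for the sea-bottom factor or complete linkage for
#' the demography factor, cut at `n_clusters`.
#'
#' @param x Numeric matrix with one row per site (rownames = site codes),
#'   e.g. from [encode_sea_bottom()] or [encode_demography()].
#' @param linkage `"ward"` or `"complete"`.
#' @param n_clusters Number of clusters to cut; must not exceed the number
#'   of sites.
#' @param prefix Label prefix (`"H"` for sea bottom, `"P"` for
#'   demography); clusters are numbered by first appearance in row order.
#' @return An object of class `sw_clustering`: `labels` (named character
#'   vector of cluster labels per site), `hclust`, `linkage`,
#'   `n_clusters`.
#' @export
cluster_sites <- function(x, linkage = c("ward", "complete"),
                          n_clusters, prefix = "C") {
  linkage <- match.arg(linkage)
  if (n_clusters > nrow(x))
    stop("n_clusters (", n_clusters, ") exceeds the number of sites (",
         nrow(x), ")")
  h <- stats::hclust(stats::dist(x),
                     method = if (linkage == "ward") "ward.D2"
                              else "complete")
  raw <- stats::cutree(h, k = n_clusters)
  first <- match(unique(raw), raw)
  relab <- match(raw, raw[sort(first)])
  labels <- stats::setNames(paste0(prefix, relab), rownames(x))
  structure(list(labels = labels, hclust = h, linkage = linkage,
                 n_clusters = n_clusters), class = "sw_clustering")
}

#' @export
print.sw_clustering <- function(x, ...) {
  cat("Site clustering (", x$linkage, " linkage, Euclidean), ",
      x$n_clusters, " clusters:\n", sep = "")
  print(x$labels)
  invisible(x)
}
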