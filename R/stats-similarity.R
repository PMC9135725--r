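#' Per-signature-whistle mean parameter table
#'
#' Collapses the per-contour feature table to one row per SW-ID with the
#' arithmetic mean of each acoustic parameter; these mean repertoire
#' vectors are the sampling units for the similarity analyses.
#'
#' @param features Feature table from [feature_table()] (columns `sw_id`,
#'   `site`, and the seven parameters).
#' @return Data frame with one row per SW-ID (`sw_id`, `site`, seven
#'   parameter means).
#' @export
mean_feature_table <- function(features) {
  stopifnot("sw_id" %in% names(features))
  ids <- unique(features$sw_id)
  rows <- lapply(ids, function(id) {
    d <- features[features$sw_id == id, ]
    out <- data.frame(sw_id = id,
                      site = if ("site" %in% names(d)) d$site[1L]
                             else NA_character_)
    for (nm in feature_names()) out[[nm]] <- mean(d[[nm]])
    out
  })
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity with fourth-root transform
#'
#' Computes pairwise Bray-Curtis dissimilarities
#' \deqn{d(x, y) = \frac{\sum_k |x_k' - y_k'|}{\sum_k (x_k' + y_k')}}
#' on the (optionally fourth-root transformed, \eqn{x' = x^{1/4}})
#' parameter table. The fourth root tames the dominance of the large
#' frequency parameters over counts and durations. Pairs of all-zero rows
#' have an undefined ratio and are reported as distance 0 with a warning.
#'
#' @param x Numeric matrix or data frame of non-negative values (rows =
#'   SW-IDs). Non-numeric columns (`sw_id`, `site`) are used as labels and
#'   dropped from the computation.
#' @param fourth_root Apply the fourth-root transform first.
#' @return A `dist` object with attributes `metric` and `transform`.
#' @export
bray_curtis <- function(x, fourth_root = TRUE) {
  labels <- NULL
  if (is.data.frame(x)) {
    if ("sw_id" %in% names(x)) labels <- x$sw_id
    x <- as.matrix(x[vapply(x, is.numeric, logical(1L))])
  }
  if (any(x < 0)) stop("Bray-Curtis requires non-negative values")
  y <- if (fourth_root) x^0.25 else x
  d <- vegan::vegdist(y, method = "bray")
  if (anyNA(d)) {
    warning("all-zero row pair(s): distance set to 0")
    d[is.na(d)] <- 0
  }
  if (!is.null(labels)) attr(d, "Labels") <- labels
  attr(d, "metric") <- "bray-curtis"
  attr(d, "transform") <- if (fourth_root) "fourth-root" else "none"
  d
}

#' Non-metric multidimensional scaling ordination
#'
#' Kruskal-style nMDS of a dissimilarity matrix (monotone regression,
#' stress-1, multiple random restarts), seeded for reproducibility.
#'
#' @param d A `dist` object (e.g. from [bray_curtis()]).
#' @param k Ordination dimension (default 2).
#' @param n_restarts Number of random restarts (best solution returned).
#' @param seed Integer seed.
#' @return An object of class `sw_nmds`: `points` (n x k coordinates),
#'   `stress` (Kruskal stress-1, in \[0, 1\]), `converged`, `n_restarts`,
#'   `seed`.
#' @export
nmds_ordination <- function(d, k = 2L, n_restarts = 50L, seed = NULL) {
  n <- attr(d, "Size")
  if (is.null(n) || n < k + 2L) stop("need at least k + 2 samples")
  with_seed(seed, {
    fit <- vegan::metaMDS(d, k = k, trymax = n_restarts, trace = 0,
                          autotransform = FALSE, wascores = FALSE)
    structure(list(points = fit$points, stress = fit$stress,
                   converged = isTRUE(fit$converged) ||
                     (is.numeric(fit$converged) && fit$converged > 0),
                   n_restarts = n_restarts, seed = seed, fit = fit),
              class = "sw_nmds")
  })
}

#' @export
print.sw_nmds <- function(x, ...) {
  cat(sprintf("nMDS ordination: %d points, k = %d, stress = %.3f%s\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "" else " (no convergent solution flag)"))
  invisible(x)
}

#' One-way ANOSIM permutation test
#'
#' Rank-based analysis of similarities. With \eqn{M = n(n-1)/2} pairwise
#' dissimilarities ranked across the whole matrix,
#' \deqn{R = \frac{\bar r_B - \bar r_W}{M / 2},}
#' the difference between the mean rank of between-group and within-group
#' pairs. R is 0 under the null hypothesis of no group structure and 1
#' when all within-group dissimilarities are smaller than every
#' between-group dissimilarity. Significance is assessed by permuting the
#' group labels; the one-sided p-value is
#' \eqn{(1 + \#\{R^{perm} \ge R\}) / (1 + n_{perm})}.
#'
#' With `exact = TRUE` all distinct assignments of the group labels are
#' enumerated instead (feasible for small n) and the p-value is the exact
#' proportion of assignments, the observed one included, with
#' \eqn{R^{perm} \ge R}.
#'
#' @param d A `dist` object.
#' @param grouping Factor (or coercible) of group labels, one per sample;
#'   at least two groups with at least two members each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all distinct label assignments instead of
#'   sampling permutations.
#' @return An object of class `sw_anosim`: `statistic` (R), `p.value`,
#'   `n_perm`, `grouping` name, `perm` (permutation R values).
#' @export
anosim_perm <- function(d, grouping, n_perm = 999L, seed = NULL,
                        exact = FALSE) {
  g <- as.factor(grouping)
  n <- attr(d, "Size")
  if (length(g) != n) stop("grouping length must match the distance matrix")
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 2L))
    stop("group(s) with fewer than two members: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  r <- rank(as.vector(d))
  M <- n * (n - 1) / 2
  ii <- unlist(lapply(seq_len(n - 1L), function(i) rep(i, n - i)))
  jj <- unlist(lapply(seq_len(n - 1L), function(i) seq(i + 1L, n)))
  r_stat <- function(gg) {
    within <- gg[ii] == gg[jj]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  obs <- r_stat(g)
  if (exact) {
    perm <- apply(multiset_permutations(as.integer(g)), 1L,
                  function(gg) r_stat(gg))
    p <- sum(perm >= obs - 1e-12) / length(perm)
    return(structure(list(statistic = obs, p.value = p,
                          n_perm = length(perm), grouping = "grouping",
                          perm = perm, exact = TRUE),
                     class = "sw_anosim"))
  }
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(...) r_stat(sample(g)),
                   numeric(1L))
    p <- (1 + sum(perm >= obs)) / (1 + n_perm)
    structure(list(statistic = obs, p.value = p, n_perm = n_perm,
                   grouping = deparse(substitute(grouping)), perm = perm,
                   exact = FALSE),
              class = "sw_anosim")
  })
}

# All distinct permutations of a multiset (rows of the returned matrix).
multiset_permutations <- function(x) {
  vals <- sort(unique(x))
  counts <- tabulate(match(x, vals))
  n <- length(x)
  rec <- function(counts, prefix) {
    if (all(counts == 0L)) return(matrix(prefix, nrow = 1L))
    do.call(rbind, lapply(which(counts > 0L), function(v) {
      cc <- counts; cc[v] <- cc[v] - 1L
      rec(cc, c(prefix, vals[v]))
    }))
  }
  rec(counts, integer())
}

#' @export
print.sw_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p.value, x$n_perm))
  invisible(x)
}
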