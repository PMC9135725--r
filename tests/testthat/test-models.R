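test_that("PCA basics: rank-1 data, variance fractions, reconstruction", {
  z <- with_seed(1, stats::rnorm(50))
  rank1 <- data.frame(a = z, b = 2 * z, c = -z + stats::rnorm(50, 0, 1e-8),
                      d = 3 * z)
  p1 <- pca_reduce(rank1, kaiser = TRUE)
  expect_gt(p1$variance_fraction[1L], 0.999)
  x <- with_seed(2, as.data.frame(matrix(stats::rnorm(7 * 40), ncol = 7)))
  names(x) <- sigwhistle:::feature_names()
  p <- pca_reduce(x, kaiser = FALSE)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  # scores %*% t(loadings) restores the standardized table
  xs <- scale(as.matrix(x))
  expect_equal(p$scores %*% t(p$loadings), xs, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(abs(crossprod(p$loadings) - diag(7)) < 1e-10))
  bad <- x; bad$min_freq <- 1
  expect_error(pca_reduce(bad), "min_freq")
  expect_error(pca_reduce(x[1:5, ]), "8 observations")
})

test_that("three correlated blocks give three Kaiser components with the declared signs", {
  tab <- simulate_feature_blocks(n = 500, seed = 9)
  p <- pca_reduce(tab, kaiser = TRUE, orient = acoustic_pca_orientation())
  expect_identical(p$k, 3L)
  L <- p$loadings
  dominant <- function(j) rownames(L)[order(abs(L[, j]),
                                            decreasing = TRUE)][1:2]
  expect_setequal(dominant(1), c("max_freq", "end_freq"))
  expect_setequal(dominant(2), c("min_freq", "start_freq"))
  expect_true(all(c("duration", "n_inflections") %in%
                    rownames(L)[order(abs(L[, 3]),
                                      decreasing = TRUE)][1:3]))
  # reporting orientation: PC1 negative on max/end, PC2 positive on
  # min/start, PC3 positive on duration/inflections, negative on range
  expect_lt(L["max_freq", 1], 0); expect_lt(L["end_freq", 1], 0)
  expect_gt(L["min_freq", 2], 0); expect_gt(L["start_freq", 2], 0)
  expect_gt(L["duration", 3], 0); expect_gt(L["n_inflections", 3], 0)
  expect_lt(L["freq_range", 3], 0)
})

glmm_sim <- function(seed, n_id = 40, n_obs = 6, effect = 0.5,
                     sd_id = 1, sd_res = 0.5) {
  with_seed(seed, {
    id <- rep(seq_len(n_id), each = n_obs)
    g <- rep(rep(c("A", "B"), each = n_id / 2), each = n_obs)
    y <- effect * (g == "B") + rep(stats::rnorm(n_id, 0, sd_id),
                                   each = n_obs) +
      stats::rnorm(n_id * n_obs, 0, sd_res)
    data.frame(y = y, g = g, sw_id = paste0("id", id))
  })
}

test_that("the mixed model recovers effects and variance components", {
  d <- glmm_sim(1, n_id = 80, n_obs = 10)
  m <- fit_glmm(d, "y", "g")
  expect_equal(m$fixed$Value[2L], 0.5, tolerance = 0.35)
  expect_equal(m$sd_intercept, 1, tolerance = 0.25)
  expect_equal(m$sd_residual, 0.5, tolerance = 0.1)
  expect_equal(m$fixed$t_value, m$fixed$Value / m$fixed$SE)
  # containment DF: observation-level vs group-level denominators
  expect_equal(m$fixed$DF[1L], 80 * 10 - 80)
  expect_equal(m$fixed$DF[2L], 80 - 2)
  expect_false(m$boundary)
})

test_that("mixed-model estimates are invariant to row order and relabelling", {
  d <- glmm_sim(2)
  m1 <- fit_glmm(d, "y", "g")
  d2 <- d[with_seed(3, sample(nrow(d))), ]
  m2 <- fit_glmm(d2, "y", "g")
  expect_equal(m1$fixed$Value, m2$fixed$Value, tolerance = 1e-8)
  d3 <- d
  d3$sw_id <- paste0("XX_", rev(as.integer(factor(d3$sw_id))))
  m3 <- fit_glmm(d3, "y", "g")
  expect_equal(m1$sd_intercept, m3$sd_intercept, tolerance = 1e-8)
})

test_that("identical group means drive the random intercept to the boundary", {
  with_seed(4, {
    d <- data.frame(y = stats::rnorm(200), g = rep(c("A", "B"), 100),
                    sw_id = rep(paste0("id", 1:10), each = 20))
  })
  d$y <- d$y - stats::ave(d$y, d$sw_id) # remove all between-id signal
  m <- fit_glmm(d, "y", "g")
  expect_true(m$boundary)
  expect_lt(m$sd_intercept, 1e-3)
})

test_that("robust outlier removal drops extreme rows and logs them", {
  ft <- with_seed(6, data.frame(
    min_freq = stats::rnorm(40, 7000, 300),
    max_freq = stats::rnorm(40, 15000, 300),
    start_freq = stats::rnorm(40, 8000, 300),
    end_freq = stats::rnorm(40, 14000, 300),
    freq_range = stats::rnorm(40, 8000, 300),
    n_inflections = stats::rpois(40, 3),
    duration = stats::rnorm(40, 1, 0.1)))
  ft$duration[1L] <- 50
  clean <- remove_outliers(ft)
  expect_false(50 %in% clean$duration)
  expect_true(50 %in% attr(clean, "removed")$duration)
  expect_gte(nrow(clean), 35L)
})

test_that("site clustering is exact on separated groups and validates k", {
  pts <- with_seed(8, rbind(
    matrix(stats::rnorm(6, 0, 0.1), ncol = 2),
    matrix(stats::rnorm(6, 20, 0.1), ncol = 2),
    cbind(stats::rnorm(3, 40, 0.1), stats::rnorm(3, 0, 0.1))))
  rownames(pts) <- paste0("s", 1:9)
  for (linkage in c("ward", "complete")) {
    cl <- cluster_sites(pts, linkage, n_clusters = 3)
    expect_length(unique(cl$labels), 3L)
    expect_length(unique(cl$labels[1:3]), 1L)
    expect_length(unique(cl$labels[4:6]), 1L)
    expect_length(unique(cl$labels[7:9]), 1L)
  }
  dup <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  cl2 <- cluster_sites(dup, "complete", n_clusters = 2)
  expect_identical(cl2$labels[["a"]], cl2$labels[["b"]])
  expect_error(cluster_sites(dup, "ward", n_clusters = 5), "exceeds")
})

test_that("the published factor structure emerges from the site metadata", {
  sites <- mediterranean_sites()
  sb <- cluster_sites(encode_sea_bottom(sites), "ward", n_clusters = 3,
                      prefix = "H")
  expect_length(unique(sb$labels), 3L)
  expect_identical(unname(sb$labels), sites$sea_bottom)
  dm <- cluster_sites(encode_demography(sites), "complete",
                      n_clusters = 4, prefix = "P")
  expect_length(unique(dm$labels), 4L)
  # same partition as the published grouping, label names aside
  expect_identical(unname(outer(dm$labels, dm$labels, "==")),
                   unname(outer(sites$demography, sites$demography, "==")))
})
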