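test_that("per-SW means collapse the feature table correctly", {
  ft <- data.frame(sw_id = c("a", "b", "b"), site = c("AL", "PC", "PC"),
                   min_freq = c(5, 6, 8), max_freq = c(10, 12, 14),
                   start_freq = c(5, 6, 8), end_freq = c(10, 12, 14),
                   freq_range = c(5, 6, 6), n_inflections = c(1, 2, 4),
                   duration = c(1, 1, 2))
  mt <- mean_feature_table(ft)
  expect_equal(nrow(mt), 2L)
  expect_equal(mt$duration[mt$sw_id == "a"], 1)
  expect_equal(mt$duration[mt$sw_id == "b"], 1.5)
  expect_equal(mt$n_inflections[mt$sw_id == "b"], 3)
  # one table row per ground-truth signature identity
  study <- make_repertoire(sw_per_site = 2, seed = 3,
                           effects = reference_effects())
  sim <- simulate_feature_study(study, obs_per_id = 4, seed = 4)
  expect_equal(nrow(mean_feature_table(sim)),
               sum(study$identities$class == "SW"))
})

test_that("Bray-Curtis matches hand computation and vegan", {
  # disjoint support: (16, 0) vs (0, 16) -> fourth roots (2,0)/(0,2) -> 1
  m <- rbind(c(16, 0), c(0, 16))
  d <- bray_curtis(m, fourth_root = TRUE)
  expect_equal(as.vector(d), 1)
  expect_equal(as.vector(bray_curtis(rbind(c(3, 7), c(3, 7)))), 0)
  x <- with_seed(5, matrix(stats::runif(60, 0, 10), nrow = 6))
  d1 <- as.matrix(bray_curtis(x, fourth_root = FALSE))
  expect_equal(d1, t(d1))
  expect_equal(unname(d1), unname(as.matrix(vegan::vegdist(x, "bray"))))
  # hand formula on one pair, with the transform
  d2 <- bray_curtis(x[1:2, ], fourth_root = TRUE)
  y <- x[1:2, ]^0.25
  expect_equal(as.vector(d2), sum(abs(y[1, ] - y[2, ])) / sum(y[1, ] + y[2, ]))
  w <- capture_warnings(
    dz <- bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 2))))
  expect_true(any(grepl("all-zero", w)))
  expect_equal(as.matrix(dz)[1, 2], 0)
})

test_that("nMDS recovers planar configurations and is seeded", {
  pts <- with_seed(1, matrix(stats::rnorm(20), ncol = 2))
  d <- stats::dist(pts)
  o1 <- nmds_ordination(d, seed = 42)
  expect_lt(o1$stress, 0.01)
  o2 <- nmds_ordination(d, seed = 42)
  expect_identical(o1$points, o2$points)
  # a genuinely 3-D configuration cannot embed in the plane
  pts3 <- with_seed(2, matrix(stats::rnorm(36), ncol = 3)) * 2
  o3 <- nmds_ordination(stats::dist(pts3), seed = 1)
  expect_gt(o3$stress, 0)
  expect_error(nmds_ordination(stats::dist(pts[1:3, ])), "k \\+ 2")
})

test_that("ANOSIM separates, matches brute force, and validates input", {
  # maximal separation: two tight clusters far apart
  pts <- rbind(matrix(stats::rnorm(8, 0, 0.1), ncol = 2),
               matrix(stats::rnorm(8, 10, 0.1), ncol = 2))
  g <- rep(c("a", "b"), each = 4)
  res <- anosim_perm(stats::dist(pts), g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  # R and exact p equal independent brute-force enumeration (20 splits)
  pts6 <- with_seed(3, matrix(stats::rnorm(12), ncol = 2))
  g6 <- rep(c("a", "b"), each = 3)
  d6 <- stats::dist(pts6)
  ex <- anosim_perm(d6, g6, exact = TRUE)
  expect_equal(ex$n_perm, 20L)
  expect_equal(ex$statistic, brute_anosim_r(d6, g6))
  expect_equal(ex$p.value, brute_anosim_exact_p(d6, g6))
  # R agrees with vegan's implementation
  v <- vegan::anosim(d6, g6, permutations = 9)
  expect_equal(ex$statistic, unname(v$statistic))
  expect_error(anosim_perm(d6, rep("a", 6)), "two groups")
  expect_error(anosim_perm(d6, c("a", "a", "a", "a", "a", "b")), "b")
})

test_that("ANOSIM permutation p-values are calibrated under the null", {
  rejections <- vapply(1:300, function(seed) {
    pts <- with_seed(seed, matrix(stats::rnorm(24), ncol = 2))
    g <- rep(c("a", "b", "c"), each = 4)
    anosim_perm(stats::dist(pts), g, n_perm = 199,
                seed = seed + 1000)$p.value <= 0.05
  }, logical(1L))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
})
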