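test_that("same seed regenerates an identical study, different seeds differ", {
  a <- make_repertoire(sw_per_site = 2, seed = 1)
  b <- make_repertoire(sw_per_site = 2, seed = 1)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- make_repertoire(sw_per_site = 2, seed = 2)
  expect_false(identical(a$prototypes, c$prototypes))
})

test_that("with zero effects, per-site parameter means differ only by noise", {
  study <- make_repertoire(sw_per_site = 3, seed = 1)
  sw <- study$identities[study$identities$class == "SW", ]
  fts <- do.call(rbind, lapply(sw$identity, function(id)
    prototype_features(study$prototypes[[id]])))
  fts$site <- sw$site
  for (nm in c("min_freq", "max_freq", "duration")) {
    p <- summary(stats::aov(fts[[nm]] ~ fts$site))[[1L]][["Pr(>F)"]][1L]
    expect_gt(p, 0.01)
  }
})

test_that("a configured min-frequency site shift is recovered in the mean", {
  # Monte-Carlo over seeds 1:200: AL prototypes get +2000 Hz on the
  # minimum frequency; the between-site difference of mean prototype
  # minima must agree with the configured shift within 3 MC standard
  # errors.
  eff <- effect_config(
    factor_shifts = list(site = list(AL = c(min_freq = 2000))))
  diffs <- vapply(1:200, function(seed) {
    st <- make_repertoire(sw_per_site = 1, effects = eff,
                          n_rewt_per_site = 0, n_ow_per_site = 0,
                          seed = seed)
    mins <- vapply(st$identities$identity, function(id)
      prototype_features(st$prototypes[[id]])$min_freq, numeric(1L))
    al <- st$identities$site == "AL"
    mean(mins[al]) - mean(mins[!al])
  }, numeric(1L))
  mc_se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 2000), 3 * mc_se)
})

test_that("identity random intercepts have the configured spread", {
  eff <- effect_config(id_sd = c(duration = 0.3))
  durs <- unlist(lapply(1:60, function(seed) {
    st <- make_repertoire(mediterranean_sites()[1, , drop = FALSE],
                          sw_per_site = 2, effects = eff,
                          n_rewt_per_site = 0, n_ow_per_site = 0,
                          seed = seed)
    vapply(st$identities$identity, function(id)
      prototype_features(st$prototypes[[id]])$duration, numeric(1L))
  }))
  base <- unlist(lapply(1:60, function(seed) {
    st <- make_repertoire(mediterranean_sites()[1, , drop = FALSE],
                          sw_per_site = 2, n_rewt_per_site = 0,
                          n_ow_per_site = 0, seed = seed)
    vapply(st$identities$identity, function(id)
      prototype_features(st$prototypes[[id]])$duration, numeric(1L))
  }))
  # variances add: var(with intercept) - var(base) ~ 0.09
  expect_equal(stats::var(durs) - stats::var(base), 0.09,
               tolerance = 0.45)
})

test_that("unknown effect levels and factors are configuration errors", {
  eff <- effect_config(
    factor_shifts = list(site = list(ATLANTIS = c(min_freq = 100))))
  expect_error(make_repertoire(sw_per_site = 1, effects = eff, seed = 1),
               "ATLANTIS")
  eff2 <- effect_config(
    factor_shifts = list(moon_phase = list(full = c(duration = 1))))
  expect_error(make_repertoire(sw_per_site = 1, effects = eff2, seed = 1),
               "moon_phase")
  expect_error(effect_config(
    factor_shifts = list(site = list(AL = c(loudness = 3)))), "loudness")
})

test_that("prototypes within a study stay mutually separated", {
  study <- make_repertoire(sw_per_site = 3, seed = 5)
  sigs <- lapply(study$prototypes, function(p)
    prototype_contour(p, dt = 0.01)[[1L]])
  n <- length(sigs)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    expect_gt(contour_distance(sigs[[i]], sigs[[j]], study$match),
              study$match$threshold)
  }
})
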