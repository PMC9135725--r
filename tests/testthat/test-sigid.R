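# Hand-built contours: linear sweep over [t0, t0 + dur].
mkct <- function(t0, dur = 0.5, f0 = 5000, f1 = 10000, session = "S1") {
  tt <- seq(0, dur, by = 0.01)
  structure(list(t = t0 + tt, f = f0 + (f1 - f0) * tt / dur,
                 identity = NA_character_),
            class = "sw_contour", session_id = session)
}
# place a unit (= one contour here) so that its END is at a given gap
# before the next unit's start
unit_train <- function(starts, dur = 0.5, ...) {
  lapply(starts, function(s) mkct(s, dur = dur, ...))
}

test_that("loop merging honours the strict 250 ms boundary", {
  # gap of 0.200 s: one two-loop unit
  u <- merge_loops(unit_train(c(0, 0.7)))  # end 0.5, start 0.7 -> gap 0.2
  expect_length(u, 1L)
  expect_identical(u[[1L]]$n_loops, 2L)
  expect_equal(u[[1L]]$t_start, 0)
  expect_equal(u[[1L]]$t_end, 1.2)
  # gap of exactly 0.250 s: two units (strictly "less than")
  u2 <- merge_loops(unit_train(c(0, 0.75)))
  expect_length(u2, 2L)
  # single contour: one single-loop unit
  u3 <- merge_loops(unit_train(0))
  expect_identical(u3[[1L]]$n_loops, 1L)
})

test_that("loop merging is order-independent, idempotent and warns on overlap", {
  cts <- unit_train(c(0, 0.7, 2, 2.6))
  u_fwd <- merge_loops(cts)
  u_rev <- merge_loops(rev(cts))
  expect_equal(vapply(u_fwd, function(u) u$t_start, numeric(1L)),
               vapply(u_rev, function(u) u$t_start, numeric(1L)))
  expect_equal(vapply(u_fwd, function(u) u$n_loops, integer(1L)),
               c(2L, 2L))
  expect_warning(merge_loops(unit_train(c(0, 0.3))), "overlap")
  # contours in different sessions are never merged
  u_sep <- merge_loops(c(unit_train(0), unit_train(0.7, session = "S2")))
  expect_length(u_sep, 2L)
})

test_that("contour distance is a shape metric", {
  a <- mkct(0)
  expect_equal(contour_distance(a, a), 0)
  shifted <- mkct(5)
  expect_equal(contour_distance(a, shifted), 0)  # time-shift invariant
  mirror <- mkct(0, f0 = 10000, f1 = 5000)
  expect_gt(contour_distance(a, mirror), match_params()$threshold)
  expect_equal(contour_distance(a, mirror), contour_distance(mirror, a))
})

test_that("the repeated-element rule is applied per session with a closed window", {
  # two matching units 5 s apart -> REWT
  cat1 <- build_rewt_catalog(merge_loops(unit_train(c(0, 5.5))))
  expect_identical(cat1$entries$status, "REWT")
  expect_identical(nrow(cat1$entries), 1L)
  # 15 s apart -> OW
  cat2 <- build_rewt_catalog(merge_loops(unit_train(c(0, 15.5))))
  expect_identical(cat2$entries$status, "OW")
  # same contour in two different sessions, never co-occurring -> OW
  cat3 <- build_rewt_catalog(merge_loops(
    c(unit_train(0), unit_train(3, session = "S2"))))
  expect_identical(cat3$entries$status, "OW")
  # boundary: end-to-start gap exactly 0.25 s qualifies
  cat4 <- build_rewt_catalog(merge_loops(unit_train(c(0, 0.75))))
  expect_identical(cat4$entries$status, "REWT")
})

test_that("the signature criterion needs four units and 75% within 1-10 s", {
  sw_status <- function(starts) {
    cat <- classify_signature(build_rewt_catalog(
      merge_loops(unit_train(starts))))
    cat$entries$status
  }
  # 4 units at 0, 3, 6, 9 s: all nearest gaps 2.5 s -> SW
  expect_identical(sw_status(c(0, 3, 6, 9)), "SW")
  # only 3 stereotyped contours -> not SW (still REWT)
  expect_identical(sw_status(c(0, 3, 6)), "REWT")
  # 4 units, one isolated at 60 s: 3/4 = 75% qualify -> SW
  expect_identical(sw_status(c(0, 3, 6, 60)), "SW")
  # 4 units each 30 s apart: 0% qualify -> not SW, and not even REWT
  expect_identical(sw_status(c(0, 30, 60, 90)), "OW")
  # gaps below 1 s: REWT (within 0.25-10) but not SW (outside 1-10)
  expect_identical(sw_status(c(0, 1.0, 2.0, 3.0)), "REWT")
})

test_that("SW-IDs propagate study-wide and non-SW sessions inherit them", {
  cts <- c(unit_train(c(0, 3, 6, 9)),            # qualifying session
           unit_train(c(0, 40), session = "S2")) # same contour, sparse
  cat <- classify_signature(build_rewt_catalog(merge_loops(cts)))
  expect_identical(nrow(cat$entries), 1L)
  expect_identical(cat$entries$status, "SW")
  expect_true(all(!is.na(cat$assignment$sw_id)))
  expect_length(unique(cat$assignment$sw_id), 1L)
})

test_that("adding a compliant unit never demotes a signature whistle", {
  base <- c(0, 3, 6, 9)
  with_extra <- c(base, 13)  # a further unit 3.5 s after the last
  s1 <- classify_signature(build_rewt_catalog(
    merge_loops(unit_train(base))))$entries$status
  s2 <- classify_signature(build_rewt_catalog(
    merge_loops(unit_train(with_extra))))$entries$status
  expect_identical(s1, "SW")
  expect_identical(s2, "SW")
})

test_that("classification equals the brute-force oracle on random sessions", {
  for (seed in 1:60) {
    rs <- random_session(seed)
    units <- merge_loops(rs$contours)
    cat <- classify_signature(build_rewt_catalog(units))
    a <- cat$assignment
    for (id in unique(rs$schedule$identity)) {
      sch <- rs$schedule[rs$schedule$identity == id, ]
      want <- oracle_status(sch$t_start, sch$t_end)
      rows <- a[sapply(a$t_start, function(ts)
        any(abs(ts - sch$t_start) < 1e-6)), ]
      expect_identical(length(unique(rows$label)), 1L)
      got <- cat$entries$status[cat$entries$label == rows$label[1L]]
      expect_identical(got, want)
    }
  }
})
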