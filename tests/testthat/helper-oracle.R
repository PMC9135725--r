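# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (explicit loops over all unit pairs and gap windows)
# and share no code with the package's classifier or ANOSIM implementation.

# Brute-force SIGID status for one identity's units in one session.
# units: data.frame with t_start, t_end.
oracle_status <- function(t_start, t_end,
                          rewt_window = c(0.25, 10),
                          sw_window = c(1, 10),
                          sw_min_units = 4, sw_min_fraction = 0.75) {
  n <- length(t_start)
  if (n < 2) return("OW")
  gap <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    lo <- max(t_start[i], t_start[j])
    hi <- min(t_end[i], t_end[j])
    gap[i, j] <- lo - hi
  }
  rewt <- FALSE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && gap[i, j] >= rewt_window[1] && gap[i, j] <= rewt_window[2])
      rewt <- TRUE
  }
  if (n >= sw_min_units) {
    ok <- 0
    for (i in seq_len(n)) {
      nearest <- Inf
      for (j in seq_len(n)) if (i != j) nearest <- min(nearest, gap[i, j])
      if (nearest >= sw_window[1] && nearest <= sw_window[2]) ok <- ok + 1
    }
    if (ok / n >= sw_min_fraction) return("SW")
  }
  if (rewt) "REWT" else "OW"
}

# A pool of well-separated prototypes shared by the random-session tests.
oracle_prototype_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) {
      study <- make_repertoire(mediterranean_sites()[1:2, ],
                               sw_per_site = 4, n_rewt_per_site = 0,
                               n_ow_per_site = 0, seed = 20260901)
      pool <<- study$prototypes
    }
    pool
  }
})

# Random unit-level session schedule with boundary-prone gaps. Returns the
# emitted loop contours plus the scheduled unit table per identity.
random_session <- function(seed, max_units = 20) {
  pool <- oracle_prototype_pool()
  # gap values probe the rule windows; exactly 0.250 is avoided because a
  # scheduled gap on the loop-merge boundary is ambiguous under
  # accumulated floating-point drift and would change the unit structure
  # itself (the exact boundary is covered by deterministic merge tests)
  boundary <- c(0.2505, 0.26, 0.9, 1.0, 1.1, 5, 9.9, 10, 10.1, 10.5, 12)
  set.seed(seed)
  n_ident <- sample(1:5, 1)
  idents <- sample(names(pool), n_ident)
  contours <- list()
  schedule <- list()
  total <- 0
  t0 <- runif(1, 0, 5)
  for (id in idents) {
    n_units <- sample(1:6, 1)
    if (total + n_units > max_units) n_units <- max_units - total
    if (n_units < 1) break
    total <- total + n_units
    for (u in seq_len(n_units)) {
      loops <- prototype_contour(pool[[id]], t0 = t0, dt = 0.02)
      for (lp in loops) {
        attr(lp, "session_id") <- "RS"
        contours[[length(contours) + 1]] <- lp
      }
      t_end <- max(loops[[length(loops)]]$t)
      schedule[[length(schedule) + 1]] <-
        data.frame(identity = id, t_start = t0, t_end = t_end)
      gap <- if (runif(1) < 0.5) sample(boundary, 1) else runif(1, 0.3, 14)
      t0 <- t_end + gap
    }
    # keep identities in disjoint time blocks so cross-identity loops are
    # never close enough to merge by timing alone
    t0 <- t0 + runif(1, 0.3, 20)
  }
  list(contours = contours, schedule = do.call(rbind, schedule))
}

# Brute-force ANOSIM R (plain double loops over the lower triangle).
brute_anosim_r <- function(d, g) {
  m <- as.matrix(d)
  n <- nrow(m)
  v <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    v <- c(v, m[i, j])
    within <- c(within, g[i] == g[j])
  }
  r <- rank(v)
  M <- n * (n - 1) / 2
  (mean(r[!within]) - mean(r[within])) / (M / 2)
}

# Exhaustive ANOSIM: every distinct assignment of the labels, enumerated
# by nested position choices (combn), which is a different algorithm from
# the package's recursive multiset enumeration.
brute_anosim_assignments <- function(g) {
  g <- as.integer(as.factor(g))
  counts <- table(g)
  assign_rec <- function(free, counts) {
    if (length(counts) == 1)
      return(matrix(rep(as.integer(names(counts)[1]), length(free)),
                    nrow = 1, dimnames = list(NULL, free)))
    v <- as.integer(names(counts)[1])
    picks <- utils::combn(free, counts[[1]], simplify = FALSE)
    do.call(rbind, lapply(picks, function(p) {
      rest <- assign_rec(setdiff(free, p), counts[-1])
      out <- matrix(v, nrow = nrow(rest), ncol = length(free),
                    dimnames = list(NULL, free))
      out[, colnames(rest)] <- rest
      out
    }))
  }
  m <- assign_rec(seq_along(g), counts)
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

brute_anosim_exact_p <- function(d, g) {
  obs <- brute_anosim_r(d, g)
  assigns <- brute_anosim_assignments(g)
  rs <- apply(assigns, 1, function(gg) brute_anosim_r(d, gg))
  sum(rs >= obs - 1e-12) / nrow(assigns)
}
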