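# Shared fixture builders. Everything is generated in code at test time.

# A saved-log tibble in the canonical shape, from a compact spec:
# list(c(start, end, min, mean, max)) per row; n_pulses derived from the
# 20 s pulse grid.
make_logs <- function(..., logger = "T01", partner = "T02",
                      pulse_interval_s = 20) {
  rows <- list(...)
  purrr::map(rows, function(r) {
    tibble::tibble(
      logger_id = logger, partner_id = partner,
      start_t = r[1], end_t = r[2],
      duration_s = r[2] - r[1],
      min_rssi = if (length(r) >= 3) r[3] else 5,
      mean_rssi = if (length(r) >= 4) r[4] else 7,
      max_rssi = if (length(r) >= 5) r[5] else 9,
      n_pulses = (r[2] - r[1]) / pulse_interval_s + 1
    )
  }) |> purrr::list_rbind()
}

# Two-sided logs for one pair: a_iv and b_iv are lists of c(start, end).
pair_logs <- function(a_iv, b_iv, a = "T01", b = "T02") {
  dplyr::bind_rows(
    if (length(a_iv)) do.call(make_logs, c(a_iv, list(logger = a, partner = b))),
    if (length(b_iv)) do.call(make_logs, c(b_iv, list(logger = b, partner = a)))
  )
}

# A deterministic two-tag trajectory: fixed positions, parallel headings.
static_traj <- function(d = 1, len_s = 60, heading2 = 0) {
  tibble::tibble(
    tag_id = rep(c("T01", "T02"), each = len_s),
    t = rep(0:(len_s - 1), 2),
    x = rep(c(0, d), each = len_s),
    y = 0,
    heading = rep(c(0, heading2), each = len_s),
    away = FALSE,
    transit = FALSE
  )
}

two_tag_world <- function(len_s = 60, n_receivers = 1,
                          receiver_positions = matrix(c(5, 5), 1)) {
  world_config(
    n_tags = 2, sim_days = 1, active_windows = list(c(0, len_s)),
    n_receivers = n_receivers, receiver_positions = receiver_positions,
    seed = 1
  )
}

# The sedentary, noiseless, threshold-free configuration used for
# reciprocity checks: colony-resident tags huddled at their nests so every
# pulse decodes on both sides.
reciprocity_config <- function(n_tags = 17, len_s = 3600, seed = 5) {
  run_config(
    world = world_config(
      n_tags = n_tags, sim_days = 1, active_windows = list(c(0, len_s)),
      n_receivers = 2, away_bout_s = 0, visit_rate_per_h = 0,
      home_radius_m = 1.5, seed = seed
    ),
    propagation = propagation_params(noise_sd = 0, shadow_sd = 0),
    tag = tag_config(detection_threshold_rssi = -1000),
    seed = seed
  )
}

# The deployment scenario used for direction-of-effect checks: a colony
# of 15 tags over 4 days of twice-daily 3 h windows.
colony_config <- function(seed, n_tags = 15, sim_days = 4) {
  run_config(
    world = world_config(
      n_tags = n_tags, sim_days = sim_days,
      active_windows = list(c(0, 10800), c(39600, 50400)),
      n_receivers = 2, n_nests = n_tags, arena = c(100, 80),
      nest_spacing_m = 24, visit_rate_per_h = 6, seed = seed
    ),
    seed = seed
  )
}

# Brute-force oracle for dyad calling: explicit connected components of
# the closed-interval overlap graph, classified straight from the
# definitions. Completely independent of call_dyads' sweep construction.
oracle_dyads <- function(a_iv, b_iv, break_gap_s = 21, stagger_s = 21) {
  iv <- rbind(
    if (length(a_iv)) cbind(do.call(rbind, a_iv), side = 1),
    if (length(b_iv)) cbind(do.call(rbind, b_iv), side = 2)
  )
  n <- nrow(iv)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- iv[i, 1] <= iv[j, 2] && iv[j, 1] <= iv[i, 2]
    }
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      while (length(queue)) {
        k <- queue[1]; queue <- queue[-1]
        if (comp[k] != 0L) next
        comp[k] <- cur
        queue <- c(queue, which(adj[k, ] & comp == 0L))
      }
    }
  }
  purrr::map(seq_len(cur), function(cid) {
    rows <- iv[comp == cid, , drop = FALSE]
    a <- rows[rows[, "side"] == 1, , drop = FALSE]
    b <- rows[rows[, "side"] == 2, , drop = FALSE]
    span <- function(m) if (nrow(m)) c(min(m[, 1]), max(m[, 2])) else NULL
    gap <- function(m) {
      if (nrow(m) < 2) return(0)
      m <- m[order(m[, 1]), , drop = FALSE]
      max(m[-1, 1] - m[-nrow(m), 2])
    }
    dy <- nrow(a) > 0 && nrow(b) > 0
    broken <- dy &&
      ((nrow(a) == 1 && nrow(b) >= 2 && gap(b) > break_gap_s) ||
         (nrow(b) == 1 && nrow(a) >= 2 && gap(a) > break_gap_s))
    staggered <- dy &&
      (abs(span(a)[1] - span(b)[1]) > stagger_s ||
         abs(span(a)[2] - span(b)[2]) > stagger_s)
    list(status = if (dy) "dyadic" else "single",
         start = min(rows[, 1]),
         n_a = nrow(a), n_b = nrow(b),
         broken = broken, staggered = staggered)
  })
}

# Enumerate all fragment sets of <= max_frag intervals whose endpoints are
# drawn (in order) from a grid of boundary points.
enumerate_sides <- function(grid, max_frag = 4) {
  out <- list(list())  # the empty side
  for (k in seq_len(min(max_frag, length(grid) %/% 2))) {
    picks <- utils::combn(seq_along(grid), 2 * k, simplify = FALSE)
    for (p in picks) {
      out[[length(out) + 1]] <-
        purrr::map(seq_len(k), ~ c(grid[p[2 * .x - 1]], grid[p[2 * .x]]))
    }
  }
  out
}
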