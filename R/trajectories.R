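#' Simulate tag trajectories
#'
#' Generates positions and headings for every tag at every active-window
#' time step. Each tag follows a mean-reverting (Ornstein-Uhlenbeck)
#' displacement process around an attractor point, hard-limited to
#' `home_radius_m`. The attractor is normally the tag's own nest; during
#' Poisson-timed "visit" events the tag relocates to another tag's nest,
#' perches close (its displacement tightens) and aligns its body with the
#' target, which is what produces strong close-proximity contacts between
#' non nest-mates. Poisson-timed "flight" excursions add brief, fast
#' out-and-back displacement bumps within the home radius. Headings evolve
#' as a smoothed random walk.
#'
#' Because displacements never exceed `home_radius_m` and nests are at
#' least `nest_spacing_m` apart, a run with `visit_rate_per_h = 0` can
#' never bring non nest-mates within `nest_spacing_m - 2 * home_radius_m`
#' of each other (6 m under the defaults).
#'
#' @param cfg A [world_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#'
#' @return A tibble with columns `tag_id`, `t` (integer seconds since the
#'   simulation epoch), `x`, `y` (meters), `heading` (radians) and `away`
#'   (logical), one row per tag per active time step, with the nest
#'   assignment available as `attr(, "nests")`.
#' @export
#' @examples
#' traj <- simulate_trajectories(world_config(n_tags = 3, sim_days = 1,
#'   active_windows = list(c(0, 600))))
#' dplyr::count(traj, tag_id)
simulate_trajectories <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "world_config"))
  ids <- tag_ids(cfg$n_tags)
  times <- active_times(cfg)
  T_ <- length(times)
  if (T_ == 0) abort("No active time steps; check `active_windows`.")
  step <- cfg$time_step_s
  hours <- T_ * step / 3600

  nests <- cfg$nests
  nest_of <- ((seq_len(cfg$n_tags) - 1) %% cfg$n_nests) + 1

  phi <- exp(-step / cfg$ou_tau_s)
  innov_sd <- cfg$ou_sd_m * sqrt(1 - phi^2)

  out <- withr::with_seed(seed, {
    # stage 1: per-tag autonomous processes (headings, OU displacement,
    # flights, foraging absences); visits are applied in stage 2 because
    # a visitor perches next to its target and aligns with it
    base <- purrr::map(seq_len(cfg$n_tags), function(i) {
      ux <- as.numeric(stats::filter(rnorm(T_, 0, innov_sd), phi, "recursive"))
      uy <- as.numeric(stats::filter(rnorm(T_, 0, innov_sd), phi, "recursive"))

      # flight excursions: smooth out-and-back bumps inside the home disc
      n_fl <- rpois(1, cfg$flight_rate_per_h * hours)
      if (n_fl > 0) {
        f_at <- sample.int(T_, n_fl, replace = TRUE)
        f_dir <- runif(n_fl, 0, 2 * pi)
        f_amp <- runif(n_fl, cfg$home_radius_m / 3, cfg$home_radius_m)
        f_dur <- pmax(2, round(runif(n_fl, 10, 40) / step))
        for (k in seq_len(n_fl)) {
          idx <- f_at[k]:min(T_, f_at[k] + f_dur[k])
          prof <- f_amp[k] * sin(pi * (seq_along(idx) - 1) / f_dur[k])
          ux[idx] <- ux[idx] + cos(f_dir[k]) * prof
          uy[idx] <- uy[idx] + sin(f_dir[k]) * prof
        }
      }

      heading <- (runif(1, 0, 2 * pi) +
                    cumsum(rnorm(T_, 0, cfg$heading_sd_rad * sqrt(step)))) %%
        (2 * pi)

      # foraging absences: alternating at-colony/away bouts; while away
      # the bird is far outside radio range of every tag and receiver
      away <- rep(FALSE, T_)
      if (cfg$away_bout_s > 0) {
        p_away <- cfg$away_bout_s / (cfg$away_bout_s + cfg$colony_bout_s)
        state <- runif(1) < p_away
        pos <- 1L
        while (pos <= T_) {
          mean_bout <- if (state) cfg$away_bout_s else cfg$colony_bout_s
          len <- max(1L, as.integer(round(rexp(1, 1 / mean_bout) / step)))
          away[pos:min(T_, pos + len - 1L)] <- state
          pos <- pos + len
          state <- !state
        }
      }
      list(ux = ux, uy = uy, heading = heading, away = away)
    })

    # stage 2: visits. A visiting bird relocates to its target's nest,
    # perches close (displacement shrunk) and aligns its body with the
    # target, as perched neighbours do. A visit is a mutual interaction:
    # it holds both birds at the colony for its duration (neither is in a
    # foraging absence while it lasts).
    visits <- purrr::list_rbind(purrr::map(seq_len(cfg$n_tags), function(i) {
      n_vis <- rpois(1, cfg$visit_rate_per_h * hours)
      if (n_vis == 0 || cfg$n_tags < 2) {
        return(tibble::tibble(visitor = integer(), target = integer(),
                              from = integer(), to = integer(),
                              near = logical(), off = numeric(),
                              ang = numeric()))
      }
      v_at <- sample.int(T_, n_vis, replace = TRUE)
      v_tgt <- sample(setdiff(seq_len(cfg$n_tags), i), n_vis, replace = TRUE)
      # most visits perch on a nearby spot a few meters off (a
      # neighbouring beam or wire); some are side-by-side contact, and
      # those affiliative contacts last longer than loose proximity
      near <- runif(n_vis) < 0.6
      mean_dur <- ifelse(near, cfg$visit_duration_s, 1.5 * cfg$visit_duration_s)
      v_dur <- pmax(1, round((40 + rexp(n_vis, 1 / mean_dur)) / step))
      tibble::tibble(
        visitor = i, target = v_tgt,
        from = v_at, to = pmin(T_, v_at + v_dur),
        near = near,
        off = runif(n_vis, 4, 7),
        ang = runif(n_vis, 0, 2 * pi)
      )
    }))

    purrr::map(seq_len(cfg$n_tags), function(i) {
      b <- base[[i]]
      away <- b$away
      ax <- rep(nests$x[nest_of[i]], T_)
      ay <- rep(nests$y[nest_of[i]], T_)
      ux <- b$ux; uy <- b$uy; heading <- b$heading
      mine <- visits[visits$visitor == i, , drop = FALSE]
      for (k in seq_len(nrow(mine))) {
        idx <- mine$from[k]:mine$to[k]
        tgt <- mine$target[k]
        # close visits are side-by-side contact; near visits keep a few
        # meters
        off <- if (mine$near[k]) mine$off[k] else 0.1
        shrink <- if (mine$near[k]) 0.3 else 0.1
        ax[idx] <- nests$x[nest_of[tgt]] + cos(mine$ang[k]) * off
        ay[idx] <- nests$y[nest_of[tgt]] + sin(mine$ang[k]) * off
        ux[idx] <- ux[idx] * shrink
        uy[idx] <- uy[idx] * shrink
        # side-by-side contact perching aligns the birds' bodies; a bird
        # perched a few meters off keeps its own orientation
        if (!mine$near[k]) {
          heading[idx] <- (base[[tgt]]$heading[idx] +
                             rnorm(length(idx), 0, 0.2)) %% (2 * pi)
        }
        away[idx] <- FALSE
      }
      # visits received hold this bird at its nest as well
      held <- visits[visits$target == i, , drop = FALSE]
      for (k in seq_len(nrow(held))) {
        away[held$from[k]:held$to[k]] <- FALSE
      }

      # the attractor moves at swallow flight speed (~8 m/s), so transits
      # past other nests are fleeting; while relocating the bird is on the
      # wing (marked `transit`)
      sl <- slew_path(ax, ay, 8 * step)
      transit <- (sl$x - ax)^2 + (sl$y - ay)^2 > 0.25
      ax <- sl$x; ay <- sl$y

      # hard clamp of the displacement to the home radius
      r <- sqrt(ux^2 + uy^2)
      over <- r > cfg$home_radius_m
      if (any(over)) {
        sc <- cfg$home_radius_m / r[over]
        ux[over] <- ux[over] * sc
        uy[over] <- uy[over] * sc
      }

      x <- pmin(pmax(ax + ux, 0), cfg$arena[1])
      y <- pmin(pmax(ay + uy, 0), cfg$arena[2])

      tibble::tibble(tag_id = ids[i], t = times, x = x, y = y,
                     heading = heading, away = away, transit = transit)
    }) |> purrr::list_rbind()
  })

  attr(out, "nests") <- dplyr::mutate(nests,
    tags = purrr::map(.data$nest, ~ ids[nest_of == .x]))
  attr(out, "cfg") <- cfg
  out
}

# Integer time grid (seconds since epoch) covering all active windows.
active_times <- function(cfg) {
  step <- cfg$time_step_s
  unlist(lapply(seq_len(cfg$sim_days) - 1, function(day) {
    lapply(cfg$active_windows, function(w) {
      seq.int(day * 86400L + w[1], day * 86400L + w[2] - step, by = step)
    })
  }))
}

#' Ground-truth contact intervals
#'
#' Scans a trajectory set for spans during which a pair of tags was within
#' `distance_m` of each other; used to validate the logging pipeline
#' against what actually happened.
#'
#' @param traj A trajectory tibble from [simulate_trajectories()].
#' @param distance_m Contact distance threshold, meters.
#' @return A tibble `tag_a`, `tag_b`, `start_t`, `end_t` (one row per
#'   contiguous sub-threshold span; `tag_a < tag_b`).
#' @export
true_contact_intervals <- function(traj, distance_m = 5) {
  ids <- sort(unique(traj$tag_id))
  wide <- traj |>
    dplyr::arrange(.data$tag_id, .data$t)
  if (!"away" %in% names(wide)) wide$away <- FALSE
  times <- sort(unique(wide$t))
  pos <- split(wide[c("t", "x", "y", "away")], wide$tag_id)
  step_gap <- if (length(times) > 1) min(diff(times)) else 1L

  res <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      a <- pos[[ids[i]]]; b <- pos[[ids[j]]]
      stopifnot(identical(a$t, b$t))
      close_ <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2) < distance_m &
        !a$away & !b$away
      # contiguous runs of TRUE, split at window gaps
      grp <- cumsum(c(TRUE, diff(a$t) > step_gap | diff(close_) != 0))
      runs <- which(close_)
      if (!length(runs)) next
      spans <- tapply(a$t[runs], grp[runs], range)
      res[[length(res) + 1]] <- tibble::tibble(
        tag_a = ids[i], tag_b = ids[j],
        start_t = vapply(spans, `[`, numeric(1), 1),
        end_t = vapply(spans, `[`, numeric(1), 2)
      )
    }
  }
  if (!length(res)) {
    return(tibble::tibble(tag_a = character(), tag_b = character(),
                          start_t = numeric(), end_t = numeric()))
  }
  purrr::list_rbind(res)
}


# Limit the speed at which an attractor series can move: the bird flies
# toward its current goal at most `v_max` meters per step.
slew_path <- function(ax, ay, v_max) {
  n <- length(ax)
  if (n < 2) return(list(x = ax, y = ay))
  x <- ax; y <- ay
  for (t in 2:n) {
    dx <- ax[t] - x[t - 1]
    dy <- ay[t] - y[t - 1]
    d <- sqrt(dx^2 + dy^2)
    if (d > v_max) {
      x[t] <- x[t - 1] + dx / d * v_max
      y[t] <- y[t - 1] + dy / d * v_max
    } else {
      x[t] <- ax[t]
      y[t] <- ay[t]
    }
  }
  list(x = x, y = y)
}
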