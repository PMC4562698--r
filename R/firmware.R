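#' Clock-saver restore time
#'
#' When a tag resets and loses its clock, the firmware restores it from the
#' last periodically saved time: restored = last saved time +
#' period / 2 + 2 seconds (a two-second startup delay plus the midpoint of
#' the unknown reset position within the save period).
#'
#' @param last_saved_t Last saved clock time, seconds.
#' @param period_s Clock-saver save period, seconds.
#' @return Restored clock time, seconds.
#' @export
#' @examples
#' clock_saver_restore(1000, 30) # 1017
clock_saver_restore <- function(last_saved_t, period_s) {
  if (any(period_s < 0)) abort("`period_s` must be non-negative.")
  last_saved_t + period_s / 2 + 2
}

#' Clock synchronization against a receiver broadcast
#'
#' Receiver stations broadcast their clock every 15 minutes. A tag hearing
#' a broadcast adopts the receiver's time if and only if the receiver's
#' clock was set more recently than the tag's own.
#'
#' @param tag_clock_set_t Time at which the tag's clock was last set.
#' @param receiver_clock_set_t Time at which the receiver's clock was last
#'   set.
#' @param receiver_time The receiver's current clock reading.
#' @param tag_time The tag's current clock reading.
#' @return A list with elements `time` (the tag's clock after the
#'   broadcast) and `set_t` (when that clock was last set).
#' @export
sync_clock <- function(tag_clock_set_t, receiver_clock_set_t,
                       receiver_time, tag_time) {
  if (receiver_clock_set_t > tag_clock_set_t) {
    list(time = receiver_time, set_t = receiver_clock_set_t)
  } else {
    list(time = tag_time, set_t = tag_clock_set_t)
  }
}

#' Create an empty tag state
#'
#' @param tag_id Identifier of the tag this state belongs to.
#' @return A `tag_state` list: open encounters, saved and downloaded logs,
#'   loss counters, clock offset, and an `alive` flag.
#' @export
new_tag_state <- function(tag_id) {
  structure(list(
    tag_id = tag_id,
    open = list(),            # partner -> c(start, last, min, max, sum, n)
    saved = list(),           # finalized logs currently in memory
    downloaded = list(),      # logs already collected by a receiver
    dropped_log_count = 0L,   # lost to full memory
    dropped_pulses = 0L,
    wiped_log_count = 0L,     # lost to battery resets
    wiped_pulses = 0L,
    ignored_pulses = 0L,      # refused: concurrent-encounter limit
    skipped_pulses = 0L,      # below threshold with no open encounter
    clock_offset_s = 0,
    clock_set_t = -Inf,
    alive = TRUE
  ), class = "tag_state")
}

# ---- internal kernel: operates on an environment holding a tag_state ----

fw_finalize <- function(env, partner) {
  e <- env$open[[partner]]
  list(
    logger_id = env$tag_id, partner_id = partner,
    start_t = e[1], end_t = e[2],
    min_rssi = e[3], max_rssi = e[4],
    mean_rssi = e[5] / e[6], n_pulses = e[6]
  )
}

fw_save <- function(env, log, cfg) {
  if (length(env$saved) < cfg$memory_capacity) {
    env$saved[[length(env$saved) + 1]] <- log
  } else {
    env$dropped_log_count <- env$dropped_log_count + 1L
    env$dropped_pulses <- env$dropped_pulses + log$n_pulses
  }
  invisible(env)
}

fw_close <- function(env, partner, cfg) {
  fw_save(env, fw_finalize(env, partner), cfg)
  env$open[[partner]] <- NULL
  invisible(env)
}

# close every open encounter whose last pulse is more than one interval
# before t (a pulse slot was missed)
fw_close_stale <- function(env, t, cfg) {
  if (!length(env$open)) return(invisible(env))
  for (partner in names(env$open)) {
    if (env$open[[partner]][2] + cfg$pulse_interval_s < t) {
      fw_close(env, partner, cfg)
    }
  }
  invisible(env)
}

fw_flush <- function(env) {
  env$downloaded <- c(env$downloaded, env$saved)
  env$saved <- list()
  invisible(env)
}

fw_reset <- function(env, t, cfg) {
  env$wiped_log_count <- env$wiped_log_count + length(env$saved)
  env$wiped_pulses <- env$wiped_pulses +
    sum(vapply(env$saved, function(l) l$n_pulses, numeric(1))) +
    sum(vapply(env$open, function(e) e[6], numeric(1)))
  env$saved <- list()
  env$open <- list()
  p <- cfg$clock_saver_period_s
  restored <- clock_saver_restore(floor(t / max(p, 1)) * p, p)
  env$clock_offset_s <- restored - t
  env$clock_set_t <- -Inf
  invisible(env)
}

fw_detect <- function(env, t, partner, rssi, cfg) {
  fw_close_stale(env, t, cfg)
  e <- env$open[[partner]]
  if (is.null(e)) {
    # the RSSI threshold gates encounter initiation only; once an
    # encounter is open every decoded pulse feeds the running statistics
    # (recorded minima can therefore fall below the threshold, down to
    # the radio's decode floor)
    if (rssi < cfg$detection_threshold_rssi) {
      env$skipped_pulses <- env$skipped_pulses + 1L
      return(invisible(env))
    }
    if (length(env$open) >= cfg$max_concurrent) {
      env$ignored_pulses <- env$ignored_pulses + 1L
      return(invisible(env))
    }
    env$open[[partner]] <- c(t, t, rssi, rssi, rssi, 1)
  } else {
    e[2] <- t
    e[3] <- min(e[3], rssi)
    e[4] <- max(e[4], rssi)
    e[5] <- e[5] + rssi
    e[6] <- e[6] + 1
    env$open[[partner]] <- e
    if (t - e[1] >= cfg$max_encounter_s) fw_close(env, partner, cfg)
  }
  invisible(env)
}

state_to_env <- function(state) list2env(unclass(state))
env_to_state <- function(env, state) {
  out <- as.list(env)[names(unclass(state))]
  structure(out, class = "tag_state")
}

#' Advance a tag state by one pulse detection
#'
#' The core firmware transition: stale open encounters (those that missed a
#' pulse slot) are closed with their end set to the last detected pulse;
#' a detection below the RSSI threshold is then ignored; otherwise it opens
#' a new encounter with that partner (subject to the concurrent-encounter
#' limit) or extends the running one, closing it immediately when it
#' reaches the encounter duration cap.
#'
#' Detections must arrive in time order; feeding an earlier detection after
#' a later one is a data error.
#'
#' @param state A [new_tag_state()].
#' @param det A one-row data frame or list with `listener_id`, `source_id`,
#'   `t`, `rssi`.
#' @param cfg A [tag_config()].
#' @return The updated `tag_state`.
#' @export
step_encounter <- function(state, det, cfg = tag_config()) {
  stopifnot(inherits(state, "tag_state"))
  if (!identical(det$listener_id, state$tag_id)) {
    abort("Detection routed to the wrong tag state.")
  }
  last_t <- max(c(-Inf, vapply(state$open, function(e) e[2], numeric(1))))
  if (det$t < last_t) {
    abort("Out-of-order detection stream.")
  }
  env <- state_to_env(state)
  fw_detect(env, det$t, det$source_id, det$rssi, cfg)
  env_to_state(env, state)
}

#' Save a finalized encounter log into tag memory
#'
#' Appends the log if memory has room; otherwise the new log is the one
#' lost and the drop counter is incremented.
#'
#' @param state A `tag_state`.
#' @param log A finalized log (list with at least `n_pulses`).
#' @param cfg A [tag_config()].
#' @return The updated `tag_state`.
#' @export
save_log <- function(state, log, cfg = tag_config()) {
  env <- state_to_env(state)
  fw_save(env, log, cfg)
  env_to_state(env, state)
}

#' Apply a battery-failure reset
#'
#' Past its battery life a tag keeps transmitting ID pulses (other tags and
#' receivers still hear it) but resets at unpredictable times: memory and
#' any open encounters are wiped, and the clock is restored through the
#' clock saver. Encounters involving such a tag are later recoverable only
#' from the healthy partner's side, which is what turns them into single
#' logs downstream.
#'
#' @param state A `tag_state`.
#' @param t Time of the reset, seconds.
#' @param cfg A [tag_config()].
#' @return The updated `tag_state`.
#' @export
apply_battery_failure <- function(state, t, cfg = tag_config()) {
  env <- state_to_env(state)
  fw_reset(env, t, cfg)
  env_to_state(env, state)
}

#' Run a full deployment over a pulse stream
#'
#' Routes every tag-side detection through its listener's firmware state
#' machine and collects the results: saved encounter logs (with daily
#' download flushes, memory-overflow drops, battery-failure wipes, the
#' concurrent-encounter limit, and clock drift/synchronization applied),
#' the receiver-station pulse table (receivers log every detection
#' individually, with no threshold), and per-tag uptime intervals.
#'
#' @param pulses Detection tibble from [generate_pulses()] (time-sorted).
#' @param tag_cfg A [tag_config()] applied to every tag.
#' @param world Optional [world_config()]; supplies the active windows
#'   (for uptime intervals and daily download flushes) and the known tag
#'   set (unknown listener ids are rejected).
#' @param battery_life_s Optional named vector of per-tag battery lives in
#'   seconds, overriding `tag_cfg$battery_life_s`.
#' @param seed Seed for battery-reset times.
#'
#' @return A list with elements `logs` (tibble: `logger_id`, `partner_id`,
#'   `start_t`, `end_t`, `duration_s`, `min_rssi`, `mean_rssi`,
#'   `max_rssi`, `n_pulses`), `receiver_log`, `uptime` (tibble `tag_id`,
#'   `start_t`, `end_t`), and `accounting` (per-tag loss counters).
#' @export
run_deployment <- function(pulses, tag_cfg = tag_config(), world = NULL,
                           battery_life_s = NULL, seed = 1L) {
  if (nrow(pulses) == 0) abort("Empty pulse stream.")
  if (is.unsorted(pulses$t)) {
    abort("Out-of-order detection stream: `pulses` must be sorted by `t`.")
  }

  is_rec <- is_receiver_id(pulses$listener_id)
  receiver_log <- pulses[is_rec, , drop = FALSE]
  tag_det <- pulses[!is_rec, , drop = FALSE]

  tags <- sort(unique(c(tag_det$listener_id, pulses$source_id)))
  if (!is.null(world)) {
    known <- tag_ids(world$n_tags)
    bad <- setdiff(tags, known)
    if (length(bad)) {
      abort(paste0("Unknown listener/source id(s): ", paste(bad, collapse = ", ")))
    }
    tags <- known
  }

  t_end <- max(pulses$t)
  flush_times <- if (!is.null(world)) {
    seq_len(world$sim_days) * 86400 - 600  # the 23:50 download window
  } else {
    numeric(0)
  }

  life <- setNames(rep(tag_cfg$battery_life_s, length(tags)), tags)
  if (!is.null(battery_life_s)) {
    life[names(battery_life_s)] <- battery_life_s
  }

  # clock model: piecewise drift, re-zeroed at each receiver sync the tag
  # can hear (a receiver heard it within half a broadcast period)
  drift <- tag_cfg$clock_drift_s_per_day / 86400
  sync_times_of <- function(tag) {
    if (drift == 0 || nrow(receiver_log) == 0) return(numeric(0))
    heard <- receiver_log$t[receiver_log$source_id == tag]
    if (!length(heard)) return(numeric(0))
    b <- seq(0, t_end + 900, by = 900)
    b[vapply(b, function(bt) any(abs(heard - bt) <= 450), logical(1))]
  }
  offset_at <- function(t, syncs) {
    if (drift == 0) return(rep(0, length(t)))
    last <- numeric(length(t))
    if (length(syncs)) {
      idx <- findInterval(t, syncs)
      last <- ifelse(idx > 0, syncs[pmax(idx, 1)], 0)
    }
    round(drift * (t - last))
  }

  logs <- list()
  acct <- list()
  for (tag in tags) {
    env <- state_to_env(new_tag_state(tag))
    d <- tag_det[tag_det$listener_id == tag, , drop = FALSE]

    resets <- numeric(0)
    if (is.finite(life[[tag]]) && life[[tag]] < t_end) {
      resets <- withr::with_seed(derive_seed(seed, paste0("battery-", tag)), {
        r <- life[[tag]] + cumsum(rexp(256, 1 / 600))
        r[r <= t_end + 600]
      })
    }
    events <- sort(c(resets, flush_times))
    ev_i <- 1L

    # a download only collects from a tag whose battery is still healthy:
    # past its life the tag resets before the download window, so the
    # memory is lost instead
    handle_event <- function(et) {
      if (et %in% resets) {
        fw_reset(env, et, tag_cfg)
      } else if (et > life[[tag]]) {
        fw_reset(env, et, tag_cfg)
      } else {
        fw_close_stale(env, et + tag_cfg$pulse_interval_s + 1, tag_cfg)
        fw_flush(env)
      }
    }

    ts <- d$t; src <- d$source_id; rs <- d$rssi
    for (k in seq_len(nrow(d))) {
      while (ev_i <= length(events) && events[ev_i] <= ts[k]) {
        handle_event(events[ev_i])
        ev_i <- ev_i + 1L
      }
      fw_detect(env, ts[k], src[k], rs[k], tag_cfg)
    }
    # end of stream: remaining events, then a final download
    while (ev_i <= length(events)) {
      handle_event(events[ev_i])
      ev_i <- ev_i + 1L
    }
    fw_close_stale(env, t_end + tag_cfg$pulse_interval_s + 1, tag_cfg)
    if (t_end > life[[tag]]) fw_reset(env, t_end, tag_cfg) else fw_flush(env)

    tl <- env$downloaded
    if (length(tl)) {
      tlog <- dplyr::bind_rows(lapply(tl, tibble::as_tibble))
      syncs <- sync_times_of(tag)
      tlog$start_t <- tlog$start_t + offset_at(tlog$start_t, syncs)
      tlog$end_t <- tlog$end_t + offset_at(tlog$end_t, syncs)
      logs[[tag]] <- tlog
    }
    acct[[tag]] <- tibble::tibble(
      tag_id = tag,
      dropped_logs = env$dropped_log_count,
      dropped_pulses = env$dropped_pulses,
      wiped_logs = env$wiped_log_count,
      wiped_pulses = env$wiped_pulses,
      ignored_pulses = env$ignored_pulses,
      skipped_pulses = env$skipped_pulses,
      saved_pulses = if (length(tl)) sum(vapply(tl, function(l) l$n_pulses, numeric(1))) else 0
    )
  }

  logs <- if (length(logs)) {
    purrr::list_rbind(unname(logs)) |>
      dplyr::mutate(duration_s = .data$end_t - .data$start_t,
                    .after = "end_t") |>
      dplyr::arrange(.data$start_t, .data$logger_id, .data$partner_id)
  } else {
    tibble::tibble(
      logger_id = character(), partner_id = character(),
      start_t = numeric(), end_t = numeric(), duration_s = numeric(),
      min_rssi = numeric(), mean_rssi = numeric(), max_rssi = numeric(),
      n_pulses = numeric()
    )
  }

  uptime <- uptime_intervals(tags, life, world, t_end)

  list(
    logs = logs,
    receiver_log = tibble::as_tibble(receiver_log),
    uptime = uptime,
    accounting = purrr::list_rbind(unname(acct))
  )
}

# Per-tag operational intervals: active windows clipped to battery life.
uptime_intervals <- function(tags, life, world, t_end) {
  purrr::map(tags, function(tag) {
    cap <- if (is.null(world)) min(life[[tag]], t_end) else life[[tag]]
    if (!is.null(world)) {
      spans <- purrr::list_rbind(lapply(seq_len(world$sim_days) - 1, function(day) {
        purrr::list_rbind(lapply(world$active_windows, function(w) {
          tibble::tibble(start_t = day * 86400 + w[1], end_t = day * 86400 + w[2])
        }))
      }))
    } else {
      spans <- tibble::tibble(start_t = 0, end_t = t_end)
    }
    spans |>
      dplyr::filter(.data$start_t < cap) |>
      dplyr::mutate(end_t = pmin(.data$end_t, cap), tag_id = tag,
                    .before = 1)
  }) |> purrr::list_rbind()
}
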