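#' Generate the pulse-detection stream
#'
#' Each tag broadcasts an ID pulse every `pulse_interval_s` seconds at a
#' per-tag random phase (real tag clocks are unsynchronized). At each pulse
#' instant inside an active window, every other tag and every receiver
#' station within radio range hears a detection whose RSSI is drawn from
#' the propagation model at the current pairwise distance and relative
#' antenna angle. Tags are treated as body-mounted and can decode each
#' other out to `p$tag_range_m`. Receiver stations listen with no RSSI
#' threshold out to `p$max_range_m` (their antennae are vertical; the
#' relative angle used is the tag heading folded against the
#' tag-to-receiver bearing).
#'
#' @param traj Trajectory tibble from [simulate_trajectories()].
#' @param cfg The [world_config()] used to build `traj`.
#' @param p A [propagation_params()].
#' @param pulse_interval_s Pulse interval, seconds.
#' @param seed Integer seed for phases and RSSI noise.
#'
#' Tags in an away (foraging) bout neither transmit within range nor hear
#' anything; their pulses simply go undetected. A pulse whose noisy RSSI
#' falls below the radio's sensitivity floor (`p$rssi_min`) fails to
#' decode and produces no detection at all — the floor is the weakest
#' decodable reading, which is why an encounter ends when a link degrades
#' rather than logging ever-lower values.
#'
#' @return A tibble `listener_id`, `source_id`, `t`, `rssi`, sorted by
#'   `t`, `listener_id`, `source_id`; per-tag pulse phases are stored in
#'   `attr(, "phases")`.
#' @export
generate_pulses <- function(traj, cfg, p = propagation_params(),
                            pulse_interval_s = 20, seed = cfg$seed + 1L) {
  if (nrow(traj) == 0) abort("Empty trajectory.")
  if (pulse_interval_s <= 0) abort("`pulse_interval_s` must be positive.")
  if (!"away" %in% names(traj)) traj$away <- FALSE
  if (!"transit" %in% names(traj)) traj$transit <- FALSE
  ids <- sort(unique(traj$tag_id))
  step <- cfg$time_step_s
  if (pulse_interval_s %% step != 0) {
    abort("`time_step_s` must divide the pulse interval.")
  }

  withr::with_seed(seed, {
    # per-tag phase on the trajectory grid
    phases <- (sample.int(pulse_interval_s %/% step, length(ids),
                          replace = TRUE) - 1L) * step
    names(phases) <- ids

    pulses <- traj |>
      dplyr::filter(!.data$away,
                    (.data$t - phases[.data$tag_id]) %% pulse_interval_s == 0) |>
      dplyr::select(source_id = "tag_id", "t",
                    sx = "x", sy = "y", sheading = "heading",
                    stransit = "transit")

    # tag listeners: join all other present tags' positions at the pulse
    # instants
    listeners <- traj |>
      dplyr::filter(!.data$away) |>
      dplyr::select(listener_id = "tag_id", "t",
                    lx = "x", ly = "y", lheading = "heading",
                    ltransit = "transit")
    tag_det <- pulses |>
      dplyr::inner_join(listeners, by = "t",
                        relationship = "many-to-many") |>
      dplyr::filter(.data$listener_id != .data$source_id) |>
      dplyr::mutate(
        dist = sqrt((.data$sx - .data$lx)^2 + (.data$sy - .data$ly)^2),
        rel = fold_angle(.data$sheading - .data$lheading)
      ) |>
      dplyr::filter(.data$dist <= p$tag_range_m)

    # a bird on the wing carries its antenna cross-polarized relative to
    # perched birds, attenuating the link in either direction
    mu <- expected_rssi(tag_det$dist, tag_det$rel, "body", p) +
      link_shadowing(tag_det$listener_id, tag_det$source_id, tag_det$t, p) -
      (tag_det$stransit | tag_det$ltransit) * p$flight_attenuation
    tag_det$rssi <- decode_rssi(mu, p, tag_det$dist)
    tag_det <- tag_det[!is.na(tag_det$rssi), , drop = FALSE]

    out <- dplyr::select(tag_det, "listener_id", "source_id", "t", "rssi")

    # receiver listeners
    if (!is.null(cfg$receiver_positions) && cfg$n_receivers > 0) {
      rec <- tibble::tibble(
        listener_id = receiver_ids(cfg$n_receivers),
        lx = cfg$receiver_positions[, 1],
        ly = cfg$receiver_positions[, 2]
      )
      rec_det <- pulses |>
        dplyr::cross_join(rec) |>
        dplyr::mutate(
          dist = sqrt((.data$sx - .data$lx)^2 + (.data$sy - .data$ly)^2),
          rel = fold_angle(.data$sheading -
                             atan2(.data$ly - .data$sy, .data$lx - .data$sx))
        ) |>
        dplyr::filter(.data$dist <= p$max_range_m)
      mu_r <- expected_rssi(rec_det$dist, rec_det$rel, "body", p) +
        link_shadowing(rec_det$listener_id, rec_det$source_id, rec_det$t, p) -
        rec_det$stransit * p$flight_attenuation
      rec_det$rssi <- decode_rssi(mu_r, p, rec_det$dist)
      rec_det <- rec_det[!is.na(rec_det$rssi), , drop = FALSE]
      out <- dplyr::bind_rows(
        out, dplyr::select(rec_det, "listener_id", "source_id", "t", "rssi")
      )
    }

    out <- dplyr::arrange(out, .data$t, .data$listener_id, .data$source_id)
    attr(out, "phases") <- phases
    out
  })
}

# Slow shadow fading: per directed link (listener hearing source), an AR(1)
# bias over successive pulses with stationary SD `p$shadow_sd` and
# correlation time `p$shadow_tau_s`. Each direction fades independently:
# the wearer's own body obstructs its receiver regardless of how well the
# reverse link is doing. Uses the current RNG stream (generate_pulses runs
# under its seed). Approximates the pulse spacing by the modal gap within
# each link when computing the AR coefficient.
link_shadowing <- function(listener_id, source_id, t, p) {
  if (p$shadow_sd == 0) return(numeric(length(t)))
  key <- paste(listener_id, source_id, sep = ">")
  ord <- order(key, t)
  sh <- numeric(length(t))
  ks <- key[ord]
  grp_start <- c(TRUE, ks[-1] != ks[-length(ks)])
  grp_id <- cumsum(grp_start)
  for (g in split(seq_along(ord), grp_id)) {
    n <- length(g)
    dt <- if (n > 1) stats::median(diff(t[ord[g]])) else p$shadow_tau_s
    phi <- exp(-max(dt, 1) / p$shadow_tau_s)
    innov <- rnorm(n, 0, p$shadow_sd * sqrt(1 - phi^2))
    innov[1] <- rnorm(1, 0, p$shadow_sd)
    sh[ord[g]] <- as.numeric(stats::filter(innov, phi, "recursive"))
  }
  sh
}


# A pulse is decoded only if its noisy RSSI reaches the sensitivity floor;
# undecoded pulses return NA (no detection). Values above the ceiling are
# reported at the ceiling.
decode_rssi <- function(mu, p, distance_m) {
  sdv <- rssi_noise_sd(distance_m, p)
  r <- round(mu + rnorm(length(mu), 0, sdv))
  r[r < p$rssi_min] <- NA_integer_
  as.integer(pmin(r, p$rssi_max))
}
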