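#' Configuration of the simulated world
#'
#' Describes the deployment arena and schedule for the synthetic-tag
#' simulator: how many tags, over how many days, during which daily
#' sampling windows, where nests and receiver stations sit, and the
#' parameters of the home-range movement model.
#'
#' The defaults mirror a small colonial-songbird deployment: 17 tags active
#' 6-9am and 5-8pm over 3 days, nests at least 20 m apart in a 60 x 40 m
#' arena, and 8 fixed receiver stations. Movement is a mean-reverting walk
#' around each tag's nest, hard-limited to `home_radius_m`, with occasional
#' within-range "flight" excursions and pairwise "visit" events during which
#' a tag relocates to another tag's nest. `visit_rate_per_h` is the knob
#' that controls how often non nest-mates come into contact.
#'
#' @param n_tags Number of tags (>= 2).
#' @param sim_days Number of simulated days.
#' @param active_windows List of `c(start, end)` clock times (`"HH:MM"`
#'   strings or seconds-of-day) during which tags are awake; must be
#'   non-overlapping within a day.
#' @param time_step_s Trajectory time step in seconds; must divide the tag
#'   pulse interval.
#' @param arena `c(width, height)` of the rectangular arena in meters.
#' @param n_nests Number of nest sites; defaults to `ceiling(n_tags / 2)`
#'   (tags are assigned to nests round-robin, so most nests hold a pair).
#' @param nest_spacing_m Minimum spacing between nest sites in meters.
#' @param n_receivers Number of fixed receiver stations.
#' @param receiver_positions Optional matrix (n x 2) of receiver coordinates;
#'   defaults to an even grid over the arena.
#' @param home_radius_m Hard limit on a tag's displacement from its current
#'   attractor (its own nest, or a visit target's nest), meters.
#' @param ou_sd_m Stationary standard deviation of the mean-reverting
#'   displacement process, meters.
#' @param ou_tau_s Relaxation time of the displacement process, seconds.
#' @param visit_rate_per_h Expected number of visit events per tag per
#'   active hour (0 disables visits).
#' @param visit_duration_s Mean visit duration, seconds (exponential).
#' @param flight_rate_per_h Expected number of flight excursions per tag per
#'   active hour.
#' @param heading_sd_rad Standard deviation of per-second heading
#'   increments, radians.
#' @param colony_bout_s Mean duration of an at-colony bout, seconds.
#' @param away_bout_s Mean duration of an away (foraging) bout, seconds.
#'   Birds spend much of their active time foraging far from the colony;
#'   an away tag is out of radio range of every tag and receiver. Set
#'   `away_bout_s = 0` to keep all tags at the colony continuously.
#' @param epoch Calendar origin used when timestamps are written to CSV.
#' @param seed Integer seed for trajectory generation.
#'
#' @return An object of class `world_config` (a validated list).
#' @export
#' @examples
#' cfg <- world_config(n_tags = 4, sim_days = 1)
#' cfg$n_tags
world_config <- function(n_tags = 17,
                         sim_days = 3,
                         active_windows = list(c("06:00", "09:00"),
                                               c("17:00", "20:00")),
                         time_step_s = 1,
                         arena = c(60, 40),
                         n_nests = NULL,
                         nest_spacing_m = 20,
                         n_receivers = 8,
                         receiver_positions = NULL,
                         home_radius_m = 7,
                         ou_sd_m = 1.5,
                         ou_tau_s = 20,
                         visit_rate_per_h = 2,
                         visit_duration_s = 120,
                         flight_rate_per_h = 6,
                         heading_sd_rad = 0.3,
                         colony_bout_s = 600,
                         away_bout_s = 900,
                         epoch = "2014-08-01 00:00:00",
                         seed = 1L) {
  if (n_tags < 2) abort("`n_tags` must be at least 2.")
  if (sim_days < 1) abort("`sim_days` must be at least 1.")
  if (time_step_s < 1) abort("`time_step_s` must be a positive integer.")
  n_nests <- n_nests %||% ceiling(n_tags / 2)
  if (n_nests < 1) abort("`n_nests` must be at least 1.")

  win <- lapply(active_windows, clock_to_seconds)
  win <- win[order(vapply(win, `[`, integer(1), 1))]
  starts <- vapply(win, `[`, integer(1), 1)
  ends <- vapply(win, `[`, integer(1), 2)
  if (any(ends <= starts)) abort("Active windows must have end > start.")
  if (length(win) > 1 && any(starts[-1] < ends[-length(win)])) {
    abort("Active windows must be non-overlapping within a day.")
  }

  # the nest grid must fit: reject arenas smaller than the nest spacing
  if (min(arena) < nest_spacing_m) {
    abort("Arena is smaller than the nest spacing; enlarge `arena` or reduce `nest_spacing_m`.")
  }

  cfg <- structure(list(
    n_tags = as.integer(n_tags),
    sim_days = as.integer(sim_days),
    active_windows = win,
    time_step_s = as.integer(time_step_s),
    arena = as.numeric(arena),
    n_nests = as.integer(n_nests),
    nest_spacing_m = nest_spacing_m,
    n_receivers = as.integer(n_receivers),
    receiver_positions = receiver_positions,
    home_radius_m = home_radius_m,
    ou_sd_m = ou_sd_m,
    ou_tau_s = ou_tau_s,
    visit_rate_per_h = visit_rate_per_h,
    visit_duration_s = visit_duration_s,
    flight_rate_per_h = flight_rate_per_h,
    heading_sd_rad = heading_sd_rad,
    colony_bout_s = colony_bout_s,
    away_bout_s = away_bout_s,
    epoch = epoch,
    seed = as.integer(seed)
  ), class = "world_config")

  # lay out nests on a grid with the requested spacing
  cfg$nests <- nest_layout(cfg)
  if (is.null(cfg$receiver_positions) && cfg$n_receivers > 0) {
    cfg$receiver_positions <- receiver_layout(cfg)
  }
  cfg
}

nest_layout <- function(cfg) {
  w <- cfg$arena[1]; h <- cfg$arena[2]; s <- cfg$nest_spacing_m
  ncol_ <- max(1, floor(w / s) + 1)
  nrow_ <- max(1, floor(h / s) + 1)
  if (ncol_ * nrow_ < cfg$n_nests) {
    abort("Arena too small to place the requested number of nests at `nest_spacing_m`.")
  }
  idx <- seq_len(cfg$n_nests) - 1
  gx <- (idx %% ncol_) * s
  gy <- (idx %/% ncol_) * s
  tibble::tibble(
    nest = seq_len(cfg$n_nests),
    x = pmin(gx, w),
    y = pmin(gy, h)
  )
}

receiver_layout <- function(cfg) {
  n <- cfg$n_receivers
  w <- cfg$arena[1]; h <- cfg$arena[2]
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  idx <- seq_len(n) - 1
  cbind(
    x = (idx %% ncol_ + 0.5) * w / ncol_,
    y = (idx %/% ncol_ + 0.5) * h / nrow_
  )
}

#' Radio propagation model parameters
#'
#' Parameters of the RSSI-versus-distance model used both to simulate pulse
#' detections and as the parametric family fitted by [fit_propagation()].
#' The expected RSSI at distance `d` (meters), relative antenna angle
#' `theta` and mount `m` is
#'
#' \deqn{\mu(d,\theta,m) = r_{ref} + s \log_{10} g(d) + G\,[m = body]
#'       - P_{max}\,(1 - e^{-d/\lambda})\,\sin\theta}
#'
#' where \eqn{g(d) = d_{sat}(1 - e^{-d/d_{sat}})} is the effective
#' distance: essentially the true distance within a few meters, flattening
#' mildly in the far field (`d_sat = Inf` recovers the pure log-distance
#' law). Noise grows mildly with distance: readings are Gaussian with
#' standard deviation `noise_sd * (1 + min(d, cap) / noise_dist_scale_m)`,
#' rounded to integers. Readings cannot exceed the ceiling `rssi_max`;
#' the floor `rssi_min` is the radio's sensitivity limit — static
#' calibration readings report it as-is, while in a moving deployment a
#' pulse below the floor simply fails to decode. The pile-up of weak
#' readings on the floor is what makes far distance bins look flat and
#' mutually indistinguishable.
#'
#' The default curve is anchored so that a body-mounted pair with parallel
#' antennae reads RSSI 40 at 0.1 m and RSSI 0 at 5 m (the two thresholds
#' used for network construction), which with the default mild saturation
#' gives a slope of -25.44 RSSI per decade of effective distance and a
#' body-mount reference of +14.49 at 1 m effective distance.
#'
#' @param rssi_at_ref Expected RSSI of a bare (pole-mounted) tag at 1 m
#'   effective distance, parallel antennae.
#' @param slope_per_log10m RSSI change per decade of effective distance
#'   (negative).
#' @param orientation_penalty_max Penalty (RSSI units) at perpendicular
#'   antennae and large distance.
#' @param orientation_ramp_m Distance scale over which the orientation
#'   penalty develops, meters.
#' @param mount_gain Additive gain (RSSI units) of an animal/saline body
#'   mount relative to a bare tag.
#' @param noise_sd Baseline noise standard deviation at zero distance.
#' @param noise_dist_scale_m Distance scale of noise growth, meters.
#' @param noise_dist_cap_m Distance beyond which the noise SD stops
#'   growing, meters.
#' @param shadow_sd Standard deviation of slow shadow fading (RSSI units).
#'   Shadowing is a per-directed-link bias that evolves as an AR(1)
#'   process with correlation time `shadow_tau_s`: bodies and obstacles
#'   block a link for stretches of time rather than per pulse, and each
#'   direction of a link fades independently. It applies to moving
#'   deployments ([generate_pulses()]); static calibration trials absorb
#'   it into their replicate and pair variance.
#' @param shadow_tau_s Correlation time of shadow fading, seconds.
#' @param flight_attenuation Extra path loss (RSSI units) on any link
#'   whose source or listener is flying between perches: a bird on the
#'   wing holds its antenna cross-polarized relative to perched birds.
#' @param rssi_min,rssi_max Hardware floor and ceiling of reported RSSI.
#' @param d_min_clamp Smallest distance used in the curve, meters (distances
#'   below are clamped; 0 m is physical contact).
#' @param d_sat Saturation scale of the effective distance, meters
#'   (`Inf` gives the pure log-distance law).
#' @param max_range_m Maximum radio range of receiver stations (elevated,
#'   with a clear antenna), meters.
#' @param tag_range_m Maximum tag-to-tag decode range in deployment
#'   conditions (body-worn, at perch height, amid clutter), meters.
#'   Pole-mounted line-of-sight calibration trials decode much farther;
#'   on animals, pulses beyond this range fail to decode at all.
#'
#' @return An object of class `propagation_params` (a validated list).
#' @export
#' @examples
#' p <- propagation_params()
#' expected_rssi(c(0.1, 5), 0, "body", p) # ~ c(40, 0)
propagation_params <- function(rssi_at_ref = NULL,
                               slope_per_log10m = NULL,
                               orientation_penalty_max = 19.5,
                               orientation_ramp_m = 0.13,
                               mount_gain = 5,
                               noise_sd = 2.5,
                               noise_dist_scale_m = 6,
                               noise_dist_cap_m = 10,
                               shadow_sd = 8,
                               flight_attenuation = 12,
                               shadow_tau_s = 600,
                               rssi_min = -17L,
                               rssi_max = 57L,
                               d_min_clamp = 0.01,
                               d_sat = 3.5,
                               max_range_m = 100,
                               tag_range_m = 12) {
  if (d_min_clamp <= 0) abort("`d_min_clamp` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (rssi_min >= rssi_max) abort("`rssi_min` must be below `rssi_max`.")

  # solve slope and reference from the two distance anchors (0.1 m -> 40,
  # 5 m -> 0; body mount, parallel) unless supplied explicitly
  g <- function(d) {
    d <- pmax(d, d_min_clamp)
    if (is.infinite(d_sat)) d else d_sat * (1 - exp(-d / d_sat))
  }
  if (is.null(slope_per_log10m)) {
    slope_per_log10m <- -40 / (log10(g(5)) - log10(g(0.1)))
  }
  if (slope_per_log10m >= 0) abort("`slope_per_log10m` must be negative.")
  if (is.null(rssi_at_ref)) {
    rssi_at_ref <- -slope_per_log10m * log10(g(5)) - mount_gain
  }

  structure(list(
    rssi_at_ref = rssi_at_ref,
    slope_per_log10m = slope_per_log10m,
    orientation_penalty_max = orientation_penalty_max,
    orientation_ramp_m = orientation_ramp_m,
    mount_gain = mount_gain,
    noise_sd = noise_sd,
    noise_dist_scale_m = noise_dist_scale_m,
    noise_dist_cap_m = noise_dist_cap_m,
    shadow_sd = shadow_sd,
    flight_attenuation = flight_attenuation,
    shadow_tau_s = shadow_tau_s,
    rssi_min = as.integer(rssi_min),
    rssi_max = as.integer(rssi_max),
    d_min_clamp = d_min_clamp,
    d_sat = d_sat,
    max_range_m = max_range_m,
    tag_range_m = tag_range_m
  ), class = "propagation_params")
}

#' Tag firmware parameters
#'
#' Settings of the simulated tag firmware: how often a tag pulses, which
#' detections it logs, how encounters are bounded, and its memory, clock
#' and battery behaviour. Defaults follow the standard small-bird
#' configuration: 20 s pulse interval, RSSI >= 0 detection threshold, 5 min
#' encounter cap, up to 30 simultaneous encounters, 300-log memory, 30 s
#' clock-saver period.
#'
#' @param pulse_interval_s Seconds between ID pulses.
#' @param detection_threshold_rssi Minimum RSSI for a pulse to enter an
#'   encounter (receiver stations log everything regardless).
#' @param max_encounter_s Encounter duration cap, seconds; must be a
#'   multiple of `pulse_interval_s`.
#' @param max_concurrent Maximum simultaneously monitored partners.
#' @param memory_capacity Maximum stored encounter logs between downloads.
#' @param clock_saver_period_s Clock-saver save period, seconds.
#' @param battery_life_s Battery life, seconds of operation (Inf = healthy
#'   for the whole deployment). After this the tag still pulses but resets
#'   at random, wiping its memory.
#' @param clock_drift_s_per_day Clock drift, seconds per day, corrected
#'   whenever the tag hears a receiver-station time broadcast.
#'
#' @return An object of class `tag_config` (a validated list).
#' @export
tag_config <- function(pulse_interval_s = 20,
                       detection_threshold_rssi = 0,
                       max_encounter_s = 300,
                       max_concurrent = 30,
                       memory_capacity = 300,
                       clock_saver_period_s = 30,
                       battery_life_s = Inf,
                       clock_drift_s_per_day = 3) {
  if (pulse_interval_s <= 0) abort("`pulse_interval_s` must be positive.")
  if (max_encounter_s <= 0 || max_encounter_s %% pulse_interval_s != 0) {
    abort("`max_encounter_s` must be a positive multiple of `pulse_interval_s`.")
  }
  if (max_concurrent < 1 || memory_capacity < 1) {
    abort("`max_concurrent` and `memory_capacity` must be positive.")
  }
  if (clock_saver_period_s < 0) abort("`clock_saver_period_s` must be non-negative.")
  structure(list(
    pulse_interval_s = as.integer(pulse_interval_s),
    detection_threshold_rssi = detection_threshold_rssi,
    max_encounter_s = as.integer(max_encounter_s),
    max_concurrent = as.integer(max_concurrent),
    memory_capacity = as.integer(memory_capacity),
    clock_saver_period_s = clock_saver_period_s,
    battery_life_s = battery_life_s,
    clock_drift_s_per_day = clock_drift_s_per_day
  ), class = "tag_config")
}

#' Log-processing thresholds
#'
#' @param merge_gap_s Same-pair logs separated by at most this many seconds
#'   are recombined (set to the pulse interval).
#' @param break_gap_s A dyadic record is "broken" when one side recorded
#'   continuously while the other has an internal gap greater than this.
#' @param stagger_s A dyadic record is "staggered" when one side overhangs
#'   the other by more than this at either end.
#' @param network_thresholds Max-RSSI thresholds at which contact networks
#'   are built.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(merge_gap_s = 20,
                            break_gap_s = 21,
                            stagger_s = 21,
                            network_thresholds = c(0, 40)) {
  structure(list(
    merge_gap_s = merge_gap_s,
    break_gap_s = break_gap_s,
    stagger_s = stagger_s,
    network_thresholds = network_thresholds
  ), class = "pipeline_config")
}

#' Full run configuration
#'
#' Bundles the world, propagation, tag and pipeline configurations with a
#' single global seed. Per-component seeds are derived deterministically
#' from the global seed so that each stage is independently reproducible.
#'
#' @param world A [world_config()].
#' @param propagation A [propagation_params()].
#' @param tag A [tag_config()].
#' @param pipeline A [pipeline_config()].
#' @param seed Global integer seed.
#' @param battery_life_s Optional named vector of per-tag battery lives
#'   (seconds of operation), overriding `tag$battery_life_s`.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(world = world_config(),
                       propagation = propagation_params(),
                       tag = tag_config(),
                       pipeline = pipeline_config(),
                       seed = 1L,
                       battery_life_s = NULL) {
  if (world$time_step_s > 1 &&
      tag$pulse_interval_s %% world$time_step_s != 0) {
    abort("`time_step_s` must divide the tag pulse interval.")
  }
  structure(list(
    world = world,
    propagation = propagation,
    tag = tag,
    pipeline = pipeline,
    seed = as.integer(seed),
    battery_life_s = battery_life_s
  ), class = "run_config")
}

#' Read and write run configurations as YAML
#'
#' The on-disk format is a key tree mirroring the four sub-configurations;
#' any omitted key takes its package default, so a partial file is valid.
#'
#' @param path Path to a YAML file.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, values) {
    if (is.null(values)) return(ctor())
    ok <- intersect(names(values), names(formals(ctor)))
    bad <- setdiff(names(values), names(formals(ctor)))
    if (length(bad)) {
      abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
    }
    do.call(ctor, values[ok])
  }
  wv <- y$world
  if (!is.null(wv$active_windows)) {
    wv$active_windows <- lapply(wv$active_windows, unlist)
  }
  run_config(
    world = build(world_config, wv),
    propagation = build(propagation_params, y$propagation),
    tag = build(tag_config, y$tag),
    pipeline = build(pipeline_config, y$pipeline),
    seed = y$seed %||% 1L,
    battery_life_s = if (!is.null(y$battery_life_s)) unlist(y$battery_life_s)
  )
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  w <- unclass(config$world)
  w$nests <- NULL
  w$receiver_positions <- NULL
  w$active_windows <- lapply(w$active_windows, as.integer)
  y <- list(
    world = w,
    propagation = unclass(config$propagation),
    tag = lapply(unclass(config$tag), function(v) {
      if (identical(v, Inf)) ".inf" else v
    }),
    pipeline = unclass(config$pipeline),
    seed = config$seed
  )
  if (!is.null(config$battery_life_s)) y$battery_life_s <- as.list(config$battery_life_s)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.world_config <- function(x, ...) {
  win <- paste(vapply(x$active_windows, function(w) {
    sprintf("%02d:%02d-%02d:%02d", w[1] %/% 3600, w[1] %% 3600 %/% 60,
            w[2] %/% 3600, w[2] %% 3600 %/% 60)
  }, character(1)), collapse = ", ")
  cat(sprintf(
    "<world_config> %d tags, %d day(s), windows %s, arena %g x %g m, %d nests, %d receivers\n",
    x$n_tags, x$sim_days, win, x$arena[1], x$arena[2], x$n_nests, x$n_receivers
  ))
  invisible(x)
}

#' @export
print.propagation_params <- function(x, ...) {
  cat(sprintf(
    "<propagation_params> slope %.2f /decade (d_sat %.1f m), ref %.2f, mount gain %.1f, orient penalty %.1f, noise %.1f*(1+d/%g), RSSI [%d, %d]\n",
    x$slope_per_log10m, x$d_sat, x$rssi_at_ref, x$mount_gain,
    x$orientation_penalty_max, x$noise_sd, x$noise_dist_scale_m,
    x$rssi_min, x$rssi_max
  ))
  invisible(x)
}

#' @export
print.tag_config <- function(x, ...) {
  cat(sprintf(
    "<tag_config> pulse %ds, threshold %g RSSI, cap %ds, %d concurrent, %d-log memory\n",
    x$pulse_interval_s, x$detection_threshold_rssi, x$max_encounter_s,
    x$max_concurrent, x$memory_capacity
  ))
  invisible(x)
}

# Stable short hash of a configuration, embedded in output headers.
config_hash <- function(config) {
  substr(rlang::hash(config), 1, 12)
}
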