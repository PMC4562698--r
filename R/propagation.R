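#' Saturating effective distance
#'
#' The monotone transform \eqn{g(d) = d_{sat}(1 - e^{-d/d_{sat}})} applied
#' to true distance before the log-distance law; with the default
#' `d_sat = Inf` this is the identity. Finite `d_sat` flattens the far
#' field while remaining strictly increasing (so expected RSSI remains
#' strictly decreasing in distance).
#'
#' @param distance_m True distance(s), meters.
#' @param p A [propagation_params()].
#' @return Effective distance(s), meters.
#' @export
effective_distance <- function(distance_m, p = propagation_params()) {
  d <- pmax(distance_m, p$d_min_clamp)
  if (is.infinite(p$d_sat)) return(d)
  p$d_sat * (1 - exp(-d / p$d_sat))
}

#' Expected RSSI at a given distance, orientation and mount
#'
#' Deterministic mean of the propagation model (no noise, no quantization,
#' no hardware clipping):
#' reference + slope x log10(effective distance) + mount gain -
#' orientation penalty. The penalty is zero for parallel antennae, grows
#' with `|sin|` of the relative antenna angle, and develops with distance
#' (at contact, orientation barely matters; at a few meters the full
#' penalty applies).
#'
#' @param distance_m Distance(s) in meters (values below `p$d_min_clamp`
#'   are clamped).
#' @param rel_orientation Relative antenna angle(s), radians. Any real
#'   angle is accepted and folded to `[0, pi/2]` (0 = parallel,
#'   `pi/2` = perpendicular).
#' @param mount `"body"` (tag on animal or saline body; default) or
#'   `"bare"` (tag alone on a pole).
#' @param p A [propagation_params()].
#'
#' @return Numeric vector of expected RSSI values (real-valued; see
#'   [sample_rssi()] for the reported integer readings).
#' @export
#' @examples
#' p <- propagation_params()
#' expected_rssi(5, 0, "body", p)    # ~ 0  (the < 5 m network threshold)
#' expected_rssi(0.1, 0, "body", p)  # ~ 40 (the < 0.1 m network threshold)
expected_rssi <- function(distance_m, rel_orientation = 0,
                          mount = c("body", "bare"),
                          p = propagation_params()) {
  mount <- match.arg(mount)
  d <- pmax(distance_m, p$d_min_clamp)
  theta <- fold_angle(rel_orientation)
  penalty <- p$orientation_penalty_max *
    (1 - exp(-d / p$orientation_ramp_m)) * sin(theta)
  p$rssi_at_ref +
    p$slope_per_log10m * log10(effective_distance(d, p)) +
    (mount == "body") * p$mount_gain -
    penalty
}

#' Distance-dependent noise standard deviation
#'
#' Noise grows linearly with distance across the calibration range and is
#' capped beyond `noise_dist_cap_m`: multipath variability increases as the
#' direct path weakens, but far links do not keep getting noisier without
#' bound.
#'
#' @inheritParams expected_rssi
#' @return Noise SD(s) in RSSI units:
#'   `noise_sd * (1 + min(d, cap) / noise_dist_scale_m)`.
#' @export
rssi_noise_sd <- function(distance_m, p = propagation_params()) {
  d <- pmin(pmax(distance_m, 0), p$noise_dist_cap_m)
  p$noise_sd * (1 + d / p$noise_dist_scale_m)
}

#' Sample a reported RSSI reading
#'
#' Adds Gaussian noise to the expected RSSI, rounds to the nearest integer
#' and clips to the hardware floor and ceiling. The noise SD grows mildly
#' with distance (see [rssi_noise_sd()]), emulating the increased
#' variability of far readings. Uses the current R RNG stream; seed the
#' session (or use [withr::with_seed()]) for reproducibility.
#'
#' @param mu Expected RSSI value(s), e.g. from [expected_rssi()].
#' @param p A [propagation_params()].
#' @param distance_m Distance(s) used to scale the noise; 0 applies the
#'   baseline `noise_sd`.
#' @return Integer RSSI reading(s) in `[p$rssi_min, p$rssi_max]`.
#' @export
sample_rssi <- function(mu, p = propagation_params(), distance_m = 0) {
  sdv <- rssi_noise_sd(distance_m, p)
  r <- round(mu + rnorm(length(mu), 0, sdv))
  as.integer(pmin(pmax(r, p$rssi_min), p$rssi_max))
}

#' Longest true encounter that can yield a single detected pulse
#'
#' Brute-force enumeration over integer-second encounter placements against
#' a periodic pulse schedule. A tag's pulses occur every `pulse_interval_s`
#' at an arbitrary (unsynchronized) phase; an encounter of integer length
#' `L` seconds starting at integer time `a` detects the pulses falling
#' inside the closed interval `[a, a + L]`. The function scans all start
#' times and a fine grid of phases and returns the largest `L` for which
#' some placement detects exactly one pulse. For the standard 20 s pulse
#' rate this is 39 s: a single detected pulse bounds the true encounter
#' below twice the pulse interval.
#'
#' @param pulse_interval_s Pulse interval, seconds.
#' @param phase_step_s Granularity of the phase grid (tag clocks are not
#'   synchronized, so phases are effectively continuous).
#' @return Largest integer encounter duration (seconds) compatible with
#'   exactly one detected pulse.
#' @export
#' @examples
#' max_single_pulse_duration(20) # 39
max_single_pulse_duration <- function(pulse_interval_s = 20,
                                      phase_step_s = 0.5) {
  ivl <- pulse_interval_s
  phases <- seq(0, ivl - phase_step_s, by = phase_step_s)
  best <- 0L
  for (L in seq_len(2 * ivl)) {           # one pulse bounds L < 2*ivl
    found <- FALSE
    for (phi in phases) {
      # pulse times phi + k*ivl; encounter [a, a+L] for a in 0..(ivl-1)
      for (a in 0:(ivl - 1)) {
        k_lo <- ceiling((a - phi) / ivl)
        k_hi <- floor((a + L - phi) / ivl)
        if (k_hi - k_lo + 1 == 1) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (found) best <- L
  }
  best
}
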