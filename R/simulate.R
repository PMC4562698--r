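#' Simulate a full tag deployment
#'
#' End-to-end synthetic deployment: trajectories, the pulse-detection
#' stream, and the firmware pass that turns detections into saved
#' encounter logs, receiver-station logs and uptime intervals. All
#' randomness derives deterministically from `config$seed`, so the same
#' configuration always reproduces the same output byte for byte.
#'
#' @param config A [run_config()].
#' @param truth Also compute ground-truth sub-5 m contact intervals from
#'   the trajectories (adds a pairwise distance scan).
#' @return A list: `trajectories`, `pulses`, `logs`, `receiver_log`,
#'   `uptime`, `accounting`, `truth` (or `NULL`), and the `config`.
#' @export
#' @examples
#' cfg <- run_config(world = world_config(n_tags = 3, sim_days = 1,
#'   active_windows = list(c(0, 900)), n_receivers = 1), seed = 7)
#' dep <- simulate_deployment(cfg)
#' nrow(dep$logs)
simulate_deployment <- function(config, truth = TRUE) {
  stopifnot(inherits(config, "run_config"))
  traj <- simulate_trajectories(config$world,
                                seed = derive_seed(config$seed, "trajectories"))
  pulses <- generate_pulses(traj, config$world, config$propagation,
                            config$tag$pulse_interval_s,
                            seed = derive_seed(config$seed, "pulses"))
  dep <- run_deployment(pulses, config$tag, config$world,
                        battery_life_s = config$battery_life_s,
                        seed = derive_seed(config$seed, "battery"))
  list(
    trajectories = traj,
    pulses = pulses,
    logs = dep$logs,
    receiver_log = dep$receiver_log,
    uptime = dep$uptime,
    accounting = dep$accounting,
    truth = if (truth) true_contact_intervals(traj, 5) else NULL,
    config = config
  )
}

#' Reconcile encounter logs into records
#'
#' The processing chain applied to a deployment's saved logs: recombine
#' split logs ([merge_gap_logs()]), call dyads and singles and annotate
#' broken/staggered structure ([call_dyads()]), and optionally restrict to
#' the tags' common uptime ([restrict_to_common_uptime()]).
#'
#' @param logs Encounter-log tibble.
#' @param pipeline A [pipeline_config()] carrying the thresholds.
#' @param uptime Optional uptime tibble; when given, records are
#'   restricted to the common uptime of all tags.
#' @return A record tibble (see [call_dyads()]).
#' @export
process_deployment <- function(logs, pipeline = pipeline_config(),
                               uptime = NULL) {
  records <- logs |>
    merge_gap_logs(max_gap_s = pipeline$merge_gap_s) |>
    call_dyads(break_gap_s = pipeline$break_gap_s,
               stagger_s = pipeline$stagger_s)
  if (!is.null(uptime)) {
    records <- restrict_to_common_uptime(records, uptime)
  }
  records
}

#' Write all outputs of a simulated deployment
#'
#' Writes `pulses.csv`, `logs.csv`, `receiver.csv`, `uptime.csv` and
#' (when present) `truth.csv` into a directory. Every file starts with a
#' comment header recording the seed and a hash of the configuration.
#'
#' @param dep Result of [simulate_deployment()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_deployment <- function(dep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- dep$config
  epoch <- cfg$world$epoch
  meta <- c(seed = cfg$seed, config = config_hash(cfg))
  write_pulses(dep$pulses, file.path(dir, "pulses.csv"), epoch, meta)
  write_encounter_logs(dep$logs, file.path(dir, "logs.csv"), epoch, meta)
  write_pulses(dep$receiver_log, file.path(dir, "receiver.csv"), epoch, meta,
               listener_col = "receiver_id")
  write_intervals(dep$uptime, file.path(dir, "uptime.csv"), epoch, meta,
                  id_col = "tag_id")
  if (!is.null(dep$truth)) {
    readr::write_csv(
      dplyr::mutate(dep$truth,
                    start_iso8601 = iso8601(.data$start_t, epoch),
                    end_iso8601 = iso8601(.data$end_t, epoch)),
      file.path(dir, "truth.csv"))
  }
  invisible(dir)
}
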