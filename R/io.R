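# CSV interchange. Core timestamps are integer seconds since the
# simulation epoch; files carry ISO-8601 UTC strings. Every writer can
# prepend "# key=value" comment headers (seed, config hash); readers skip
# comment lines.

write_with_meta <- function(df, path, meta = NULL) {
  if (!is.null(meta)) {
    writeLines(paste0("# ", paste(names(meta), meta, sep = "=",
                                  collapse = " ")), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Read and write encounter-log CSV files
#'
#' The canonical interchange format of the pipeline:
#' `logger_id,partner_id,start_iso8601,end_iso8601,duration_s,min_rssi,mean_rssi,max_rssi,n_pulses`.
#'
#' @param logs Encounter-log tibble (integer-second `start_t`/`end_t`).
#' @param path CSV path.
#' @param epoch Calendar origin for the ISO-8601 conversion.
#' @param meta Optional named character vector written as a `#` comment
#'   header.
#' @return `write_encounter_logs()` returns `path` invisibly;
#'   `read_encounter_logs()` returns the tibble with integer-second
#'   times restored.
#' @export
write_encounter_logs <- function(logs, path,
                                 epoch = "2014-08-01 00:00:00",
                                 meta = NULL) {
  out <- tibble::tibble(
    logger_id = logs$logger_id,
    partner_id = logs$partner_id,
    start_iso8601 = iso8601(logs$start_t, epoch),
    end_iso8601 = iso8601(logs$end_t, epoch),
    duration_s = logs$end_t - logs$start_t,
    min_rssi = logs$min_rssi,
    mean_rssi = logs$mean_rssi,
    max_rssi = logs$max_rssi,
    n_pulses = logs$n_pulses
  )
  write_with_meta(out, path, meta)
}

#' @rdname write_encounter_logs
#' @export
read_encounter_logs <- function(path, epoch = "2014-08-01 00:00:00") {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  required <- c("logger_id", "partner_id", "start_iso8601", "end_iso8601",
                "min_rssi", "mean_rssi", "max_rssi", "n_pulses")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Malformed encounter-log CSV; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    logger_id = df$logger_id,
    partner_id = df$partner_id,
    start_t = from_iso8601(df$start_iso8601, epoch),
    end_t = from_iso8601(df$end_iso8601, epoch),
    duration_s = from_iso8601(df$end_iso8601, epoch) -
      from_iso8601(df$start_iso8601, epoch),
    min_rssi = df$min_rssi,
    mean_rssi = df$mean_rssi,
    max_rssi = df$max_rssi,
    n_pulses = df$n_pulses
  )
}

#' Read and write pulse-detection CSV files
#'
#' Format: `listener_id,source_id,t_iso8601,rssi` (for receiver tables the
#' listener column is named `receiver_id`).
#'
#' @param pulses Detection tibble (`listener_id`, `source_id`, `t`,
#'   `rssi`).
#' @param path CSV path.
#' @param epoch Calendar origin.
#' @param meta Optional comment-header metadata.
#' @param listener_col Column name used on disk for the listener.
#' @return `write_pulses()` returns `path` invisibly; `read_pulses()` the
#'   tibble with integer-second `t`.
#' @export
write_pulses <- function(pulses, path, epoch = "2014-08-01 00:00:00",
                         meta = NULL, listener_col = "listener_id") {
  out <- tibble::tibble(
    "{listener_col}" := pulses$listener_id,
    source_id = pulses$source_id,
    t_iso8601 = iso8601(pulses$t, epoch),
    rssi = pulses$rssi
  )
  write_with_meta(out, path, meta)
}

#' @rdname write_pulses
#' @export
read_pulses <- function(path, epoch = "2014-08-01 00:00:00",
                        listener_col = NULL) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  lcol <- listener_col %||%
    intersect(c("listener_id", "receiver_id"), names(df))[1]
  if (is.na(lcol) || !all(c("source_id", "t_iso8601", "rssi") %in% names(df))) {
    abort("Malformed pulse CSV; expected listener_id/receiver_id, source_id, t_iso8601, rssi.")
  }
  tibble::tibble(
    listener_id = df[[lcol]],
    source_id = df$source_id,
    t = from_iso8601(df$t_iso8601, epoch),
    rssi = df$rssi
  )
}

# interval tables (uptime, truth)
write_intervals <- function(df, path, epoch = "2014-08-01 00:00:00",
                            meta = NULL, id_col = "tag_id") {
  out <- tibble::tibble(
    "{id_col}" := df[[id_col]],
    start_iso8601 = iso8601(df$start_t, epoch),
    end_iso8601 = iso8601(df$end_t, epoch)
  )
  write_with_meta(out, path, meta)
}

#' @rdname write_encounter_logs
#' @export
read_uptime <- function(path, epoch = "2014-08-01 00:00:00") {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  tibble::tibble(
    tag_id = df$tag_id,
    start_t = from_iso8601(df$start_iso8601, epoch),
    end_t = from_iso8601(df$end_iso8601, epoch)
  )
}

#' Read and write reconciled record CSV files
#'
#' One row per encounter record with pair ids, status, broken/staggered
#' flags, per-side spans and RSSI summaries, and fragment counts.
#'
#' @param records Record tibble from [call_dyads()].
#' @param path CSV path.
#' @param epoch Calendar origin.
#' @param meta Optional comment-header metadata.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   the tibble with integer-second times restored.
#' @export
write_records <- function(records, path, epoch = "2014-08-01 00:00:00",
                          meta = NULL) {
  iso_or_na <- function(t) ifelse(is.na(t), NA_character_, iso8601(t, epoch))
  out <- records |>
    dplyr::mutate(
      start = iso_or_na(.data$start_t),
      end = iso_or_na(.data$end_t),
      start_a = iso_or_na(.data$start_a), end_a = iso_or_na(.data$end_a),
      start_b = iso_or_na(.data$start_b), end_b = iso_or_na(.data$end_b)
    ) |>
    dplyr::select("pair_id", "tag_a", "tag_b", "status", "broken",
                  "staggered", "start", "end", "duration_s",
                  "start_a", "end_a", "min_rssi_a", "mean_rssi_a",
                  "max_rssi_a", "n_fragments_a",
                  "start_b", "end_b", "min_rssi_b", "mean_rssi_b",
                  "max_rssi_b", "n_fragments_b",
                  "overhang_head_s", "overhang_tail_s")
  write_with_meta(out, path, meta)
}

#' @rdname write_records
#' @export
read_records <- function(path, epoch = "2014-08-01 00:00:00") {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  parse_or_na <- function(x) {
    ifelse(is.na(x), NA_real_, from_iso8601(x, epoch))
  }
  df |>
    dplyr::mutate(
      start_t = parse_or_na(.data$start),
      end_t = parse_or_na(.data$end),
      start_a = parse_or_na(.data$start_a),
      end_a = parse_or_na(.data$end_a),
      start_b = parse_or_na(.data$start_b),
      end_b = parse_or_na(.data$end_b)
    ) |>
    dplyr::select(-"start", -"end") |>
    dplyr::mutate(record_id = dplyr::row_number(), .before = 1)
}

#' Read and write calibration-trial CSV files
#'
#' Format:
#' `pair_id,kind,distance_m,orientation,mount,replicate,rssi`.
#'
#' @param records Calibration tibble.
#' @param path CSV path.
#' @param meta Optional comment-header metadata.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` the tibble.
#' @export
write_calibration <- function(records, path, meta = NULL) {
  out <- records[c("pair_id", "kind", "distance_m", "orientation", "mount",
                   "replicate", "rssi")]
  write_with_meta(out, path, meta)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  required <- c("pair_id", "kind", "distance_m", "orientation", "mount",
                "replicate", "rssi")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Malformed calibration CSV; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(df)
}
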