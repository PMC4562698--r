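#' Recombine split encounter logs
#'
#' The firmware closes an encounter after a single missed pulse slot, so a
#' genuine encounter with an intermittent detection produces several short
#' logs. Logs from the same logger for the same partner separated by at
#' most `max_gap_s` (the pulse rate) are recombined: the merged log spans
#' the first start to the last end, min/max RSSI are the extrema, mean
#' RSSI is the pulse-count-weighted mean, and pulse counts add. Output
#' logs for a pair are therefore separated by more than `max_gap_s`;
#' merging is idempotent.
#'
#' @param logs Encounter-log tibble (columns as produced by
#'   [run_deployment()]: `logger_id`, `partner_id`, `start_t`, `end_t`,
#'   `min_rssi`, `mean_rssi`, `max_rssi`, `n_pulses`).
#' @param max_gap_s Maximum inter-log gap (next start minus previous end)
#'   to recombine, seconds.
#' @return A tibble of merged logs with an `n_fragments` column counting
#'   how many saved logs each merged log absorbed.
#' @export
merge_gap_logs <- function(logs, max_gap_s = 20) {
  if (nrow(logs) == 0) {
    return(dplyr::mutate(logs, n_fragments = integer(0)))
  }
  out <- logs |>
    dplyr::mutate(start_t = as.numeric(.data$start_t),
                  end_t = as.numeric(.data$end_t)) |>
    dplyr::group_by(.data$logger_id, .data$partner_id) |>
    dplyr::arrange(.data$start_t, .by_group = TRUE) |>
    dplyr::mutate(
      overlap = .data$start_t < dplyr::lag(.data$end_t, default = -Inf),
      grp = cumsum(dplyr::coalesce(
        .data$start_t - dplyr::lag(.data$end_t) > max_gap_s, TRUE))
    )
  if (any(out$overlap)) {
    abort("Overlapping same-pair logs from one logger: the firmware cannot produce these.")
  }
  out |>
    dplyr::group_by(.data$logger_id, .data$partner_id, .data$grp) |>
    dplyr::summarise(
      start_t = min(.data$start_t),
      end_t = max(.data$end_t),
      min_rssi = min(.data$min_rssi),
      mean_rssi = sum(.data$mean_rssi * .data$n_pulses) / sum(.data$n_pulses),
      max_rssi = max(.data$max_rssi),
      n_pulses = sum(.data$n_pulses),
      n_fragments = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-"grp") |>
    dplyr::mutate(duration_s = .data$end_t - .data$start_t, .after = "end_t") |>
    dplyr::arrange(.data$start_t, .data$logger_id, .data$partner_id)
}

#' Call dyadic and single encounter records
#'
#' Reconciles merged logs across the two members of each unordered tag
#' pair. Complementary logs (Tag A about B, and B about A) whose closed
#' time intervals overlap — sharing at least one common second, endpoint
#' touching included — belong to the same encounter. Overlap is chained:
#' if one side's continuous log spans two fragments on the other side, all
#' three belong to one record (the broken-log topology). Each connected
#' component becomes one `EncounterRecord`: `dyadic` when both sides are
#' present, `single` otherwise, so records = dyads + singles always.
#'
#' Records carry per-side spans, fragment counts, largest internal
#' fragment gaps and RSSI summaries; [classify_broken()] and
#' [classify_staggered()] turn those into flags (applied here with the
#' supplied thresholds).
#'
#' @param merged_logs Output of [merge_gap_logs()] over all tags' logs.
#' @param break_gap_s Broken-log gap threshold, seconds.
#' @param stagger_s Staggered-log overhang threshold, seconds.
#' @return A tibble with one row per encounter record: `pair_id`, `tag_a`,
#'   `tag_b` (`tag_a` < `tag_b`), `status`, per-side `start/end/rssi`
#'   summaries, fragment structure, and `broken`/`staggered` annotations.
#' @export
call_dyads <- function(merged_logs, break_gap_s = 21, stagger_s = 21) {
  if (nrow(merged_logs) == 0) {
    return(empty_records())
  }
  lg <- merged_logs |>
    dplyr::mutate(
      tag_a = pmin(.data$logger_id, .data$partner_id),
      tag_b = pmax(.data$logger_id, .data$partner_id),
      side = ifelse(.data$logger_id == .data$tag_a, "a", "b")
    ) |>
    dplyr::group_by(.data$tag_a, .data$tag_b) |>
    dplyr::arrange(.data$start_t, .data$end_t, .by_group = TRUE) |>
    # chained closed-interval overlap: a new component starts when a log
    # begins strictly after everything seen so far has ended
    dplyr::mutate(
      comp = cumsum(.data$start_t >
                      dplyr::lag(cummax(.data$end_t), default = -Inf))
    ) |>
    dplyr::ungroup()

  side_summary <- function(df) {
    df |>
      dplyr::group_by(.data$tag_a, .data$tag_b, .data$comp, .data$side) |>
      dplyr::arrange(.data$start_t, .by_group = TRUE) |>
      dplyr::summarise(
        start = min(.data$start_t),
        end = max(.data$end_t),
        min_rssi = min(.data$min_rssi),
        mean_rssi = sum(.data$mean_rssi * .data$n_pulses) / sum(.data$n_pulses),
        max_rssi = max(.data$max_rssi),
        n_pulses = sum(.data$n_pulses),
        n_fragments = dplyr::n(),
        gap_max = if (dplyr::n() > 1) {
          max(.data$start_t[-1] - .data$end_t[-dplyr::n()])
        } else {
          0
        },
        .groups = "drop"
      )
  }

  rec <- side_summary(lg) |>
    tidyr::pivot_wider(
      names_from = "side",
      values_from = c("start", "end", "min_rssi", "mean_rssi", "max_rssi",
                      "n_pulses", "n_fragments", "gap_max"),
      names_glue = "{.value}_{side}"
    )
  # pivot_wider drops absent sides entirely for pairs seen on one side only
  for (col in c("start", "end", "min_rssi", "mean_rssi", "max_rssi",
                "n_pulses", "n_fragments", "gap_max")) {
    for (s in c("a", "b")) {
      nm <- paste0(col, "_", s)
      if (!nm %in% names(rec)) rec[[nm]] <- NA_real_
    }
  }

  rec <- rec |>
    dplyr::mutate(
      status = ifelse(!is.na(.data$start_a) & !is.na(.data$start_b),
                      "dyadic", "single"),
      start_t = pmin(.data$start_a, .data$start_b, na.rm = TRUE),
      end_t = pmax(.data$end_a, .data$end_b, na.rm = TRUE),
      duration_s = .data$end_t - .data$start_t,
      n_fragments_a = tidyr::replace_na(.data$n_fragments_a, 0),
      n_fragments_b = tidyr::replace_na(.data$n_fragments_b, 0)
    ) |>
    dplyr::arrange(.data$start_t, .data$tag_a, .data$tag_b) |>
    dplyr::mutate(pair_id = paste(.data$tag_a, .data$tag_b, sep = "-"),
                  record_id = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"comp")

  rec |>
    classify_broken(gap_s = break_gap_s) |>
    classify_staggered(overhang_s = stagger_s)
}

empty_records <- function() {
  tibble::tibble(
    record_id = integer(), pair_id = character(),
    tag_a = character(), tag_b = character(), status = character(),
    start_a = numeric(), end_a = numeric(), min_rssi_a = numeric(),
    mean_rssi_a = numeric(), max_rssi_a = numeric(), n_pulses_a = numeric(),
    n_fragments_a = numeric(), gap_max_a = numeric(),
    start_b = numeric(), end_b = numeric(), min_rssi_b = numeric(),
    mean_rssi_b = numeric(), max_rssi_b = numeric(), n_pulses_b = numeric(),
    n_fragments_b = numeric(), gap_max_b = numeric(),
    start_t = numeric(), end_t = numeric(), duration_s = numeric(),
    broken = logical(), staggered = logical(),
    overhang_head_s = numeric(), overhang_tail_s = numeric()
  )
}

#' Flag broken records
#'
#' A dyadic record is broken when one tag recorded a single continuous log
#' while the other tag split the same encounter into two or more logs with
#' an internal gap exceeding `gap_s`. (Gaps at or below the merge
#' threshold were recombined upstream, so the only candidate gaps are
#' those above the pulse rate.)
#'
#' @param records Record tibble from [call_dyads()].
#' @param gap_s Gap threshold, seconds.
#' @return `records` with a logical `broken` column (re)computed.
#' @export
classify_broken <- function(records, gap_s = 21) {
  dplyr::mutate(records,
    broken = .data$status == "dyadic" &
      ((.data$n_fragments_a == 1 & .data$n_fragments_b >= 2 &
          .data$gap_max_b > gap_s) |
         (.data$n_fragments_b == 1 & .data$n_fragments_a >= 2 &
            .data$gap_max_a > gap_s))
  )
}

#' Flag staggered records
#'
#' A dyadic record is staggered when one side's log extends beyond the
#' other's by more than `overhang_s` at the head, the tail, or both.
#'
#' @param records Record tibble from [call_dyads()].
#' @param overhang_s Overhang threshold, seconds.
#' @return `records` with `staggered`, `overhang_head_s` and
#'   `overhang_tail_s` columns (re)computed (overhangs are `NA` for
#'   singles).
#' @export
classify_staggered <- function(records, overhang_s = 21) {
  dplyr::mutate(records,
    overhang_head_s = abs(.data$start_a - .data$start_b),
    overhang_tail_s = abs(.data$end_a - .data$end_b),
    staggered = .data$status == "dyadic" &
      (.data$overhang_head_s > overhang_s |
         .data$overhang_tail_s > overhang_s)
  )
}

#' Restrict records to the common uptime of all tags
#'
#' Network matrices must only contain data from periods when every tag was
#' operational. Computes the intersection of all tags' uptime intervals
#' and keeps records whose full encounter window lies inside it (records
#' straddling a cutoff are removed).
#'
#' @param records Record tibble from [call_dyads()].
#' @param uptime Tibble `tag_id`, `start_t`, `end_t` from
#'   [run_deployment()].
#' @return The filtered record tibble; warns and returns an empty tibble
#'   if the tags share no common uptime.
#' @export
restrict_to_common_uptime <- function(records, uptime) {
  common <- common_uptime(uptime)
  if (nrow(common) == 0) {
    warn("Tags share no common uptime; returning no records.")
    return(records[0, , drop = FALSE])
  }
  keep <- vapply(seq_len(nrow(records)), function(i) {
    any(records$start_t[i] >= common$start_t &
          records$end_t[i] <= common$end_t)
  }, logical(1))
  records[keep, , drop = FALSE]
}

# Intersection over tags of each tag's union of uptime intervals.
common_uptime <- function(uptime) {
  per_tag <- split(uptime[c("start_t", "end_t")], uptime$tag_id)
  merge_union <- function(iv) {
    iv <- iv[order(iv$start_t), , drop = FALSE]
    out <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start_t[i] <= out$end_t[nrow(out)]) {
        out$end_t[nrow(out)] <- max(out$end_t[nrow(out)], iv$end_t[i])
      } else {
        out <- rbind(out, iv[i, , drop = FALSE])
      }
    }
    out
  }
  intersect2 <- function(x, y) {
    res <- list()
    for (i in seq_len(nrow(x))) {
      s <- pmax(x$start_t[i], y$start_t)
      e <- pmin(x$end_t[i], y$end_t)
      ok <- s <= e
      if (any(ok)) res[[length(res) + 1]] <- data.frame(start_t = s[ok], end_t = e[ok])
    }
    if (!length(res)) return(data.frame(start_t = numeric(), end_t = numeric()))
    do.call(rbind, res)
  }
  acc <- merge_union(per_tag[[1]])
  for (k in seq_along(per_tag)[-1]) {
    acc <- intersect2(acc, merge_union(per_tag[[k]]))
    if (nrow(acc) == 0) break
  }
  tibble::as_tibble(acc)
}
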