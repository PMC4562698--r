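det <- function(t, rssi, listener = "T01", source = "T02") {
  list(listener_id = listener, source_id = source, t = t, rssi = rssi)
}

run_pulses <- function(pulses, cfg = tag_config(), ...) {
  run_deployment(pulses, cfg, ...)
}

pulse_tbl <- function(times, rssi, listener = "T01", source = "T02") {
  tibble::tibble(listener_id = listener, source_id = source,
                 t = times, rssi = rssi)
}

test_that("a clean pulse train becomes one log with running statistics", {
  out <- run_pulses(pulse_tbl(c(0, 20, 40), c(5, 9, 7)))
  lg <- out$logs[out$logs$logger_id == "T01", ]
  expect_identical(nrow(lg), 1L)
  expect_equal(lg$start_t, 0)
  expect_equal(lg$end_t, 40)
  expect_equal(lg$duration_s, 40)
  expect_equal(lg$min_rssi, 5)
  expect_equal(lg$max_rssi, 9)
  expect_equal(lg$mean_rssi, 7)
  expect_equal(lg$n_pulses, 3)
})

test_that("one missed pulse slot splits an encounter into zero-duration logs", {
  out <- run_pulses(pulse_tbl(c(0, 60), c(5, 5)))
  lg <- out$logs[out$logs$logger_id == "T01", ]
  expect_identical(nrow(lg), 2L)
  expect_equal(lg$duration_s, c(0, 0))
  expect_equal(lg$n_pulses, c(1, 1))
})

test_that("continuous proximity is chopped at the five-minute cap", {
  times <- seq(0, 400, by = 20)
  out <- run_pulses(pulse_tbl(times, rep(10, length(times))))
  lg <- out$logs[out$logs$logger_id == "T01", ]
  expect_identical(nrow(lg), 2L)
  expect_equal(lg$duration_s[1], 300)
  expect_equal(lg$start_t[2], 320)
  expect_equal(max(lg$duration_s), 300)
})

test_that("the threshold gates initiation but not continuation", {
  cfg <- tag_config(detection_threshold_rssi = 0)
  # opening pulse below threshold: nothing logged
  out <- run_pulses(pulse_tbl(c(0, 20), c(-5, -3)), cfg)
  expect_identical(nrow(out$logs[out$logs$logger_id == "T01", ]), 0L)
  # once open, sub-threshold pulses feed the running minimum
  out2 <- run_pulses(pulse_tbl(c(0, 20, 40), c(6, -9, 3)), cfg)
  lg <- out2$logs[out2$logs$logger_id == "T01", ]
  expect_identical(nrow(lg), 1L)
  expect_equal(lg$min_rssi, -9)
  expect_equal(lg$max_rssi, 6)
  expect_gte(lg$max_rssi, cfg$detection_threshold_rssi)
})

test_that("step_encounter mirrors the deployment kernel and rejects disorder", {
  cfg <- tag_config()
  st <- new_tag_state("T01")
  st <- step_encounter(st, det(0, 5), cfg)
  st <- step_encounter(st, det(20, 9), cfg)
  expect_identical(length(st$open), 1L)
  expect_error(step_encounter(st, det(10, 5), cfg), "Out-of-order")
  # a later pulse from another partner closes the stale encounter
  st2 <- step_encounter(st, det(100, 4, source = "T03"), cfg)
  expect_identical(length(st2$saved), 1L)
  expect_equal(st2$saved[[1]]$end_t, 20)
})

test_that("memory overflow drops the newest logs and counts them", {
  cfg <- tag_config(memory_capacity = 3)
  # four separate encounters (gaps > interval close each one)
  times <- c(0, 60, 120, 180)
  out <- run_pulses(pulse_tbl(times, rep(5, 4)), cfg)
  acct <- out$accounting[out$accounting$tag_id == "T01", ]
  expect_identical(nrow(out$logs[out$logs$logger_id == "T01", ]), 3L)
  expect_identical(acct$dropped_logs, 1L)
  expect_equal(acct$dropped_pulses, 1)
})

test_that("save_log drops beyond capacity; a flush frees memory", {
  cfg <- tag_config(memory_capacity = 2)
  st <- new_tag_state("T01")
  lg <- list(logger_id = "T01", partner_id = "T02", start_t = 0, end_t = 0,
             min_rssi = 5, max_rssi = 5, mean_rssi = 5, n_pulses = 1)
  for (i in 1:3) st <- save_log(st, lg, cfg)
  expect_identical(length(st$saved), 2L)
  expect_identical(st$dropped_log_count, 1L)
  # a download empties memory; subsequent saves succeed
  st$downloaded <- c(st$downloaded, st$saved)
  st$saved <- list()
  st <- save_log(st, lg, cfg)
  expect_identical(length(st$saved), 1L)
})

test_that("clock saver restores last saved time plus half period plus two", {
  expect_equal(clock_saver_restore(1000, 30), 1017)
  expect_equal(clock_saver_restore(0, 30), 17)
  expect_equal(clock_saver_restore(123, 0), 125)
})

test_that("clock sync adopts the receiver time only when set more recently", {
  up <- sync_clock(tag_clock_set_t = 10, receiver_clock_set_t = 50,
                   receiver_time = 1000, tag_time = 990)
  expect_equal(up$time, 1000)
  expect_equal(up$set_t, 50)
  same <- sync_clock(tag_clock_set_t = 60, receiver_clock_set_t = 50,
                     receiver_time = 1000, tag_time = 990)
  expect_equal(same$time, 990)
})

test_that("battery failure wipes memory while the tag keeps pulsing", {
  st <- new_tag_state("T01")
  lg <- list(logger_id = "T01", partner_id = "T02", start_t = 0, end_t = 0,
             min_rssi = 5, max_rssi = 5, mean_rssi = 5, n_pulses = 1)
  st <- save_log(st, lg)
  st <- apply_battery_failure(st, 1000, tag_config())
  expect_identical(length(st$saved), 0L)
  expect_identical(st$wiped_log_count, 1L)
  # clock restored through the clock saver: offset within the save period
  expect_lte(abs(st$clock_offset_s), tag_config()$clock_saver_period_s / 2 + 2)

  # a dead-battery tag records nothing while its healthy partner logs on
  pulses <- dplyr::bind_rows(
    pulse_tbl(seq(0, 200, 20), rep(8, 11), "T01", "T02"),
    pulse_tbl(seq(10, 210, 20), rep(8, 11), "T02", "T01")
  ) |> dplyr::arrange(t)
  out <- run_deployment(pulses, tag_config(),
                        battery_life_s = c(T02 = 0), seed = 1)
  expect_gt(nrow(out$logs[out$logs$logger_id == "T01", ]), 0)
  expect_identical(nrow(out$logs[out$logs$logger_id == "T02", ]), 0L)
  # infinite battery life leaves everything intact
  out2 <- run_deployment(pulses, tag_config(), seed = 1)
  expect_gt(nrow(out2$logs[out2$logs$logger_id == "T02", ]), 0)
})

test_that("deployment rejects disordered streams and unknown listeners", {
  bad <- pulse_tbl(c(40, 0), c(5, 5))
  expect_error(run_deployment(bad), "Out-of-order")
  cfg <- two_tag_world()
  alien <- pulse_tbl(0, 5, listener = "T09", source = "T01")
  expect_error(run_deployment(alien, world = cfg), "Unknown")
})

test_that("the concurrent-encounter limit refuses extra partners", {
  cfg <- tag_config(max_concurrent = 2)
  pulses <- dplyr::bind_rows(
    pulse_tbl(0, 5, source = "T02"),
    pulse_tbl(1, 5, source = "T03"),
    pulse_tbl(2, 5, source = "T04")   # third simultaneous partner
  )
  out <- run_deployment(pulses, cfg)
  acct <- out$accounting[out$accounting$tag_id == "T01", ]
  expect_identical(acct$ignored_pulses, 1L)
  expect_identical(nrow(out$logs[out$logs$logger_id == "T01", ]), 2L)
})

test_that("every detection is accounted for across the deployment", {
  cfg <- colony_config(3, n_tags = 6, sim_days = 1)
  dep <- simulate_deployment(cfg, truth = FALSE)
  tag_det <- dep$pulses[!startsWith(dep$pulses$listener_id, "R"), ]
  acct <- dep$accounting
  total <- sum(acct$saved_pulses) + sum(acct$dropped_pulses) +
    sum(acct$wiped_pulses) + sum(acct$ignored_pulses) +
    sum(acct$skipped_pulses)
  expect_identical(as.integer(total), nrow(tag_det))
  expect_equal(sum(dep$logs$n_pulses), sum(acct$saved_pulses))
})

test_that("saved logs satisfy the log invariants under a noisy deployment", {
  cfg <- colony_config(4, n_tags = 8, sim_days = 1)
  dep <- simulate_deployment(cfg, truth = FALSE)
  lg <- dep$logs
  tcfg <- cfg$tag
  expect_true(all(lg$duration_s <= tcfg$max_encounter_s))
  expect_true(all(lg$duration_s >= 0))
  expect_true(all(lg$min_rssi <= lg$mean_rssi + 1e-9))
  expect_true(all(lg$mean_rssi <= lg$max_rssi + 1e-9))
  expect_true(all(lg$max_rssi >= tcfg$detection_threshold_rssi))
  expect_true(all(lg$n_pulses == lg$duration_s / tcfg$pulse_interval_s + 1))
  expect_true(all(lg$duration_s[lg$n_pulses == 1] == 0))
  expect_true(all(lg$duration_s %% tcfg$pulse_interval_s == 0))
})
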