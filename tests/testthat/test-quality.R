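# Build a dyadic record table directly, bypassing the simulator, so the
# statistics can be checked against closed forms.
synthetic_dyads <- function(n, max_a, max_b, start = NULL) {
  tibble::tibble(
    record_id = seq_len(n),
    pair_id = "T01-T02", tag_a = "T01", tag_b = "T02",
    status = "dyadic",
    start_a = start %||% rep(0, n), end_a = (start %||% rep(0, n)) + 100,
    min_rssi_a = max_a - 5, mean_rssi_a = max_a - 2, max_rssi_a = max_a,
    n_pulses_a = 6, n_fragments_a = 1L, gap_max_a = 0,
    start_b = start %||% rep(0, n), end_b = (start %||% rep(0, n)) + 100,
    min_rssi_b = max_b - 5, mean_rssi_b = max_b - 2, max_rssi_b = max_b,
    n_pulses_b = 6, n_fragments_b = 1L, gap_max_b = 0,
    start_t = start %||% rep(0, n), end_t = (start %||% rep(0, n)) + 100,
    duration_s = 100,
    broken = FALSE, staggered = FALSE,
    overhang_head_s = 0, overhang_tail_s = 0
  )
}

test_that("perfect reciprocity yields an all-zero difference table", {
  rec <- synthetic_dyads(20, max_a = rep(30, 20), max_b = rep(30, 20))
  rs <- reciprocity_stats(rec)
  expect_identical(nrow(rs), 4L)
  expect_true(all(rs$mean_abs_diff == 0))
  expect_true(all(rs$n == 20))
})

test_that("independent side noise matches the folded-normal mean", {
  n <- 4000
  withr::with_seed(31, {
    rec <- synthetic_dyads(n,
                           max_a = rnorm(n, 20, 3),
                           max_b = rnorm(n, 20, 3))
  })
  rs <- reciprocity_stats(rec)
  # |N(0, 3*sqrt(2))| has mean 3*sqrt(2)*sqrt(2/pi) = 6/sqrt(pi)
  expect_equal(rs$mean_abs_diff[rs$measure == "max_rssi"],
               6 / sqrt(pi), tolerance = 0.05)
})

test_that("reciprocity differences ignore the side labelling", {
  withr::with_seed(8, {
    rec <- synthetic_dyads(50, max_a = rnorm(50, 25, 4),
                           max_b = rnorm(50, 20, 4))
  })
  swap <- rec
  a_cols <- grep("_a$", names(rec), value = TRUE)
  b_cols <- sub("_a$", "_b", a_cols)
  swap[a_cols] <- rec[b_cols]
  swap[b_cols] <- rec[a_cols]
  rs1 <- reciprocity_stats(rec)
  rs2 <- reciprocity_stats(swap)
  expect_equal(rs1$mean_abs_diff, rs2$mean_abs_diff)
  expect_equal(rs1$sd_abs_diff, rs2$sd_abs_diff)
})

test_that("an empty dyad set produces an empty table with a warning", {
  rec <- synthetic_dyads(5, max_a = rep(10, 5), max_b = rep(10, 5))
  rec$status <- "single"
  expect_warning(rs <- reciprocity_stats(rec), "dyadic")
  expect_identical(nrow(rs), 0L)
})

test_that("constant predictors are excluded from the dyad model", {
  withr::with_seed(9, {
    rec <- synthetic_dyads(60, max_a = rnorm(60, 20, 4),
                           max_b = rnorm(60, 20, 4))
  })
  rec$status[1:30] <- "single"
  rec$start_b[1:30] <- NA_real_
  rec$end_b[1:30] <- NA_real_
  rec$min_rssi_b[1:30] <- NA_real_
  rec$mean_rssi_b[1:30] <- NA_real_
  rec$max_rssi_b[1:30] <- NA_real_
  # duration is constant by construction here
  expect_warning(fit <- fit_dyad_probability(rec), "constant predictor")
  expect_false("duration" %in% tidy(fit)$term)
})

test_that("the dyad model does not invent effects under the null", {
  ok <- 0
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- 200
      rec <- synthetic_dyads(n, max_a = rnorm(n, 20, 5),
                             max_b = rnorm(n, 20, 5))
      rec$duration_s <- rexp(n, 1 / 60)
      rec$end_t <- rec$start_t + rec$duration_s
      rec$status <- sample(c("dyadic", "single"), n, replace = TRUE)
      fit <- suppressWarnings(fit_dyad_probability(rec))
      z <- tidy(fit)$statistic[-1]
      if (all(abs(z) < 3, na.rm = TRUE)) ok <- ok + 1
    }
  })
  expect_gte(ok, 90)
})

test_that("threshold censoring and duration drive dyadic status in deployments", {
  cfg <- colony_config(1, n_tags = 10, sim_days = 2)
  dep <- simulate_deployment(cfg, truth = FALSE)
  rec <- process_deployment(dep$logs, cfg$pipeline, dep$uptime)
  fit <- suppressWarnings(
    fit_dyad_probability(rec, predictors = c("min_rssi", "duration")))
  co <- tidy(fit)
  expect_gt(co$estimate[co$term == "min_rssi"], 0)
  expect_gt(co$estimate[co$term == "duration"], 0)
})

test_that("dyadic fraction never rises when the threshold is raised", {
  cfg0 <- colony_config(2, n_tags = 8, sim_days = 1)
  fracs <- vapply(c(-17, 0, 20, 30), function(thr) {
    cfg <- run_config(world = cfg0$world, propagation = cfg0$propagation,
                      tag = tag_config(detection_threshold_rssi = thr),
                      seed = cfg0$seed)
    dep <- simulate_deployment(cfg, truth = FALSE)
    rec <- process_deployment(dep$logs, cfg$pipeline, dep$uptime)
    if (nrow(rec) == 0) return(0)
    mean(rec$status == "dyadic")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0.02))
})

test_that("broken logs pair with their nearest-duration unbroken partner", {
  rec <- synthetic_dyads(3, max_a = c(20, 25, 30), max_b = c(20, 25, 30))
  rec$broken <- c(TRUE, FALSE, FALSE)
  rec$duration_s <- c(100, 95, 300)
  rec$start_t <- c(0, 500, 1000)
  m <- match_broken_logs(rec)
  expect_identical(nrow(m), 1L)
  expect_identical(m$unbroken_id, 2L)
  expect_equal(m$duration_diff, 5)

  # equal-duration candidates resolve to the earlier start
  rec2 <- rec
  rec2$duration_s <- c(100, 100, 100)
  rec2$start_t <- c(0, 900, 400)
  m2 <- match_broken_logs(rec2)
  expect_identical(m2$unbroken_id, 3L)
})

test_that("greedy duration matching beats random pairing", {
  cfg <- colony_config(3, n_tags = 12, sim_days = 2)
  dep <- simulate_deployment(cfg, truth = FALSE)
  rec <- process_deployment(dep$logs, cfg$pipeline, dep$uptime)
  m <- match_broken_logs(rec)
  greedy <- mean(abs(m$duration_diff))
  dy <- rec[rec$status == "dyadic", ]
  br <- dy$duration_s[dy$broken]
  un <- dy$duration_s[!dy$broken]
  rand <- withr::with_seed(5, {
    vapply(1:100, function(i) {
      mean(abs(br - sample(un, length(br))))
    }, numeric(1))
  })
  expect_lt(greedy, mean(rand))
})

test_that("identical groups compare as identical", {
  rec <- synthetic_dyads(8, max_a = rep(20, 8), max_b = rep(20, 8))
  rec$broken <- rep(c(TRUE, FALSE), each = 4)
  m <- match_broken_logs(rec)
  bs <- broken_vs_unbroken_summary(m, rec)
  expect_true(all(bs$diff == 0))
  expect_true(all(bs$cohens_d == 0))
  # spread of identical-min/max rows is max - min = 5 by construction
  expect_true(all(bs$measure %in% c("max_rssi", "min_rssi", "mean_rssi",
                                    "spread_rssi")))
})
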