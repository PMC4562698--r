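# Records with prescribed per-pair maximum RSSI values.
net_records <- function(pairs, max_rssi, dyadic = TRUE) {
  n <- length(max_rssi)
  tibble::tibble(
    record_id = seq_len(n),
    pair_id = vapply(pairs, function(p) paste(sort(p), collapse = "-"), ""),
    tag_a = vapply(pairs, function(p) sort(p)[1], ""),
    tag_b = vapply(pairs, function(p) sort(p)[2], ""),
    status = ifelse(dyadic, "dyadic", "single"),
    start_a = 0, end_a = 100, min_rssi_a = 0, mean_rssi_a = max_rssi / 2,
    max_rssi_a = max_rssi, n_pulses_a = 6, n_fragments_a = 1L, gap_max_a = 0,
    start_b = ifelse(dyadic, 0, NA_real_),
    end_b = ifelse(dyadic, 100, NA_real_),
    min_rssi_b = ifelse(dyadic, 0, NA_real_),
    mean_rssi_b = ifelse(dyadic, max_rssi / 2 - 1, NA_real_),
    max_rssi_b = ifelse(dyadic, max_rssi - 2, NA_real_),
    n_pulses_b = ifelse(dyadic, 6, NA_real_),
    n_fragments_b = ifelse(dyadic, 1L, 0L),
    gap_max_b = ifelse(dyadic, 0, NA_real_),
    start_t = 0, end_t = 100, duration_s = 100,
    broken = FALSE, staggered = FALSE,
    overhang_head_s = 0, overhang_tail_s = 0
  )
}

test_that("edge weights count threshold-passing encounters once each", {
  rec <- net_records(
    pairs = list(c("T01", "T02"), c("T01", "T02"), c("T01", "T03"),
                 c("T02", "T03"), c("T01", "T02")),
    max_rssi = c(-3, 5, 12, 41, 50)
  )
  n0 <- build_network(rec, 0)
  expect_equal(sum(n0$weights) / 2, 4)   # four encounters reach 0+
  n40 <- build_network(rec, 40)
  expect_equal(sum(n40$weights) / 2, 2)
  # a dyadic record adds one, not two
  expect_equal(n0$weights["T02", "T03"], 1L)
  # thresholds below every value count every record
  expect_equal(sum(build_network(rec, -100)$weights) / 2, nrow(rec))
  # matrix invariants
  expect_true(isSymmetric(n0$weights))
  expect_true(all(diag(n0$weights) == 0))
})

test_that("a dyadic record counts by the larger of its two sides", {
  rec <- net_records(list(c("T01", "T02")), max_rssi = 41)
  # side b carries 39: the record still passes a threshold of 40
  expect_equal(sum(build_network(rec, 40)$weights) / 2, 1)
  expect_equal(sum(build_network(rec, 42)$weights) / 2, 0)
})

test_that("density is the proportion of connected pairs", {
  rec <- net_records(
    pairs = list(c("T01", "T02"), c("T01", "T03"), c("T01", "T04"),
                 c("T02", "T03"), c("T02", "T04"), c("T03", "T04")),
    max_rssi = rep(10, 6)
  )
  expect_equal(network_density(build_network(rec, 0)), 1)
  empty <- build_network(rec, 99, tags = sprintf("T%02d", 1:4))
  expect_equal(network_density(empty), 0)
  # 17 nodes, 30 connected pairs
  pairs <- utils::combn(sprintf("T%02d", 1:17), 2, simplify = FALSE)[1:30]
  rec17 <- net_records(pairs, rep(10, 30))
  net17 <- build_network(rec17, 0, tags = sprintf("T%02d", 1:17))
  expect_equal(network_density(net17), 30 / 136)
  one_node <- build_network(rec[0, ], 0, tags = "T01")
  expect_error(network_density(one_node), "fewer than two")
})

test_that("higher-threshold networks nest inside lower-threshold ones", {
  cfg <- colony_config(9, n_tags = 10, sim_days = 2)
  dep <- simulate_deployment(cfg, truth = FALSE)
  rec <- process_deployment(dep$logs, cfg$pipeline, dep$uptime)
  thr <- c(-17, 0, 20, 40)
  nets <- lapply(thr, function(t) build_network(rec, t, tags = tag_ids(10)))
  for (k in seq_along(thr)[-1]) {
    lo <- nets[[k - 1]]$weights
    hi <- nets[[k]]$weights
    expect_true(all(hi <= lo))
    expect_true(all(lo[hi > 0] > 0))
  }
  dens <- vapply(nets, network_density, numeric(1))
  expect_true(all(diff(dens) <= 0))
})

test_that("all three export formats round-trip losslessly", {
  rec <- net_records(
    pairs = list(c("T01", "T02"), c("T02", "T03")),
    max_rssi = c(30, 45)
  )
  sex <- c(T01 = "F", T02 = "M", T03 = "F")
  net <- build_network(rec, 0, tags = names(sex), sex = sex)

  for (fmt in c("edgelist", "matrix", "graphml")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_identical(back$weights, net$weights)
    expect_equal(back$threshold, net$threshold)
  }
  # graphml retains the node attribute
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, "graphml")
  expect_identical(read_network(path, "graphml")$nodes$sex, unname(sex))
  # one edge element per nonzero pair
  expect_identical(sum(grepl("<edge ", readLines(path))), 2L)
  expect_error(write_network(net, path, "xlsx"))
})

test_that("the igraph view and plot builder work on a small network", {
  rec <- net_records(list(c("T01", "T02")), max_rssi = 10)
  net <- build_network(rec, 0)
  g <- as_igraph(net)
  expect_equal(igraph::gorder(g), 2)
  expect_equal(igraph::E(g)$weight, 1)
  pl <- autoplot(net)
  expect_s3_class(pl, "ggplot")
})
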