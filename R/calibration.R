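#' Simulate a tag-tag calibration trial table
#'
#' Emulates a field calibration: pairs of tags are held at fixed distances
#' in both antenna orientations, with a handful of replicate RSSI readings
#' per condition. Readings are drawn from the propagation model plus
#' per-tag and per-pair random intercepts (real tags differ slightly).
#'
#' @param p A [propagation_params()].
#' @param n_pairs Number of distinct tag pairs.
#' @param distances_m Distance grid, meters.
#' @param orientations Orientations tested (`"parallel"`,
#'   `"perpendicular"`).
#' @param mount Mount method for all trials: `"saline"`, `"carcass"`
#'   (both body-like) or `"pole"` (bare tag).
#' @param replicates Replicate readings per condition.
#' @param pair_sd,tag_sd SDs of pair- and tag-level random intercepts,
#'   RSSI units.
#' @param placement_sd,placement_ramp_m Between-placement (multipath)
#'   variability: each pair x distance x orientation setup carries a
#'   random offset with SD
#'   `placement_sd * (1 - exp(-(d / placement_ramp_m)^2))`.
#'   Ground-reflection interference makes mid- and far-range readings
#'   depend sensitively on exact antenna placement, while the direct path
#'   dominates at close range; replicate readings within one setup share
#'   the same offset.
#' @param seed Integer seed.
#' @return A tibble `pair_id`, `kind`, `tag_1`, `tag_2`, `distance_m`,
#'   `orientation`, `mount`, `replicate`, `rssi`.
#' @export
simulate_calibration <- function(p = propagation_params(),
                                 n_pairs = 11,
                                 distances_m = c(0, 0.1, 0.5, 1, 2, 5, 10),
                                 orientations = c("parallel", "perpendicular"),
                                 mount = c("saline", "carcass", "pole"),
                                 replicates = 3,
                                 pair_sd = 1,
                                 tag_sd = 0.5,
                                 placement_sd = 10,
                                 placement_ramp_m = 4,
                                 seed = 1L) {
  mount <- match.arg(mount)
  mnt <- if (mount == "pole") "bare" else "body"
  withr::with_seed(seed, {
    tag1 <- sprintf("C%02da", seq_len(n_pairs))
    tag2 <- sprintf("C%02db", seq_len(n_pairs))
    tag_eff <- rnorm(2 * n_pairs, 0, tag_sd)
    names(tag_eff) <- c(tag1, tag2)
    pair_eff <- rnorm(n_pairs, 0, pair_sd)

    df <- tidyr::expand_grid(
      pair = seq_len(n_pairs),
      distance_m = distances_m,
      orientation = orientations,
      replicate = seq_len(replicates)
    )
    theta <- ifelse(df$orientation == "perpendicular", pi / 2, 0)
    cell <- interaction(df$pair, df$distance_m, df$orientation, drop = TRUE)
    cell_eff <- rnorm(nlevels(cell)) * placement_sd
    cell_scale <- 1 - exp(-(df$distance_m / placement_ramp_m)^2)
    mu <- expected_rssi(df$distance_m, theta, mnt, p) +
      pair_eff[df$pair] + tag_eff[tag1[df$pair]] + tag_eff[tag2[df$pair]] +
      cell_eff[as.integer(cell)] * cell_scale
    tibble::tibble(
      pair_id = sprintf("P%02d", df$pair),
      kind = "tag-tag",
      tag_1 = tag1[df$pair],
      tag_2 = tag2[df$pair],
      distance_m = df$distance_m,
      orientation = df$orientation,
      mount = mount,
      replicate = df$replicate,
      rssi = sample_rssi(mu, p, df$distance_m)
    )
  })
}

#' Simulate a tag-receiver calibration trial table
#'
#' One tag is tested against each receiver station at a small set of
#' distances; receiver stations carry larger station-level biases than
#' tags do, which is what the receiver-variability analysis quantifies.
#'
#' @inheritParams simulate_calibration
#' @param n_receivers Number of receiver stations.
#' @param receiver_bias_sd SD of per-station RSSI bias, RSSI units.
#' @return A tibble shaped like [simulate_calibration()] output with
#'   `kind = "tag-receiver"` and `pair_id` the receiver id.
#' @export
simulate_receiver_calibration <- function(p = propagation_params(),
                                          n_receivers = 8,
                                          distances_m = c(1, 10),
                                          orientations = c("parallel",
                                                           "perpendicular"),
                                          replicates = 3,
                                          receiver_bias_sd = 3,
                                          seed = 2L) {
  withr::with_seed(seed, {
    bias <- rnorm(n_receivers, 0, receiver_bias_sd)
    df <- tidyr::expand_grid(
      receiver = seq_len(n_receivers),
      distance_m = distances_m,
      orientation = orientations,
      replicate = seq_len(replicates)
    )
    theta <- ifelse(df$orientation == "perpendicular", pi / 2, 0)
    mu <- expected_rssi(df$distance_m, theta, "body", p) + bias[df$receiver]
    tibble::tibble(
      pair_id = sprintf("R%d", df$receiver),
      kind = "tag-receiver",
      tag_1 = "T01",
      tag_2 = sprintf("R%d", df$receiver),
      distance_m = df$distance_m,
      orientation = df$orientation,
      mount = "saline",
      replicate = df$replicate,
      rssi = sample_rssi(mu, p, df$distance_m)
    )
  })
}

#' Fit the propagation model to calibration trials
#'
#' Fits linear mixed models of RSSI on distance, antenna orientation and
#' their interaction, with pair-level random intercepts, by REML
#' (lme4/lmerTest). Two fixed-effect parameterizations are fitted and
#' both reported: distance as `log10` of the saturating effective distance
#' (the parameterization of the simulator, whose distance coefficient is
#' the propagation slope per decade) and distance linear in meters (the
#' conventional field parameterization).
#'
#' Readings at the hardware floor or ceiling are censored, not noisy, and
#' would bias the slope; distance bins in which more than
#' `censored_bin_max_frac` of readings sit at a limit are excluded from
#' the fit, as are any remaining clipped rows.
#'
#' @param records Calibration tibble (see [simulate_calibration()]); needs
#'   at least two distances and two pairs.
#' @param d_sat Saturation scale used for the effective-distance
#'   transform, meters.
#' @param p Reference [propagation_params()] supplying the hardware limits
#'   and defaults carried into the estimated parameter set.
#' @param censored_bin_max_frac Maximum tolerated fraction of clipped
#'   readings in a distance bin.
#' @return An object of class `propagation_fit`: coefficient table
#'   (`$coefficients`), both model objects (`$log_fit`, `$linear_fit`),
#'   variance components (`$varcomp`), the estimated
#'   [propagation_params()] (`$params`), and bookkeeping about excluded
#'   bins. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_propagation <- function(records, d_sat = propagation_params()$d_sat,
                            p = propagation_params(),
                            censored_bin_max_frac = 0.25) {
  if (length(unique(records$distance_m)) < 2) {
    abort("Singular design: need at least two distances to fit a slope.")
  }
  if (length(unique(records$pair_id)) < 2) {
    abort("Need at least two pairs to separate pair effects.")
  }

  clipped <- records$rssi >= p$rssi_max | records$rssi <= p$rssi_min
  frac <- tapply(clipped, records$distance_m, mean)
  drop_bins <- as.numeric(names(frac))[frac > censored_bin_max_frac]
  keep <- !(records$distance_m %in% drop_bins) & !clipped
  dat <- records[keep, , drop = FALSE]
  if (length(unique(dat$distance_m)) < 2) {
    abort("Too few uncensored distance bins to fit a slope.")
  }

  pp <- p
  pp$d_sat <- d_sat
  dat$log_eff_d <- log10(effective_distance(dat$distance_m, pp))
  dat$orientation <- factor(dat$orientation,
                            levels = c("parallel", "perpendicular"))
  # replicate readings within one physical setup share a multipath offset
  dat$setup <- interaction(dat$pair_id, dat$distance_m, dat$orientation,
                           drop = TRUE)

  quiet_lmer <- function(formula) {
    withCallingHandlers(
      suppressMessages(lmerTest::lmer(formula, data = dat)),
      warning = function(w) {
        if (grepl("converge|boundary|singular", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  log_fit <- quiet_lmer(rssi ~ log_eff_d * orientation +
                          (1 | pair_id) + (1 | setup))
  linear_fit <- quiet_lmer(rssi ~ distance_m * orientation +
                             (1 | pair_id) + (1 | setup))

  coefs <- purrr::list_rbind(purrr::imap(
    list(log_distance = log_fit, linear_distance = linear_fit),
    function(fit, nm) {
      sm <- as.data.frame(summary(fit)$coefficients)
      tibble::tibble(
        model = nm,
        term = rownames(sm),
        estimate = sm[["Estimate"]],
        std_error = sm[["Std. Error"]],
        df = sm[["df"]],
        statistic = sm[["t value"]],
        p_value = sm[["Pr(>|t|)"]]
      )
    }
  ))

  vc <- as.data.frame(lme4::VarCorr(log_fit))
  varcomp <- tibble::tibble(
    group = vc$grp, variance = vc$vcov, sd = vc$sdcor
  )

  est <- p
  est$d_sat <- d_sat
  est$slope_per_log10m <-
    coefs$estimate[coefs$model == "log_distance" & coefs$term == "log_eff_d"]
  # intercept is body-mount at 1 m effective distance, parallel antennae
  est$rssi_at_ref <-
    coefs$estimate[coefs$model == "log_distance" & coefs$term == "(Intercept)"] -
    p$mount_gain
  orient_term <- coefs$estimate[coefs$model == "log_distance" &
                                  coefs$term == "orientationperpendicular"]
  if (length(orient_term)) {
    est$orientation_penalty_max <- max(0, -orient_term)
  }

  structure(list(
    coefficients = coefs,
    log_fit = log_fit,
    linear_fit = linear_fit,
    varcomp = varcomp,
    params = est,
    dropped_bins = drop_bins,
    n_used = nrow(dat),
    n_censored = sum(clipped)
  ), class = "propagation_fit")
}

#' @export
print.propagation_fit <- function(x, ...) {
  cat("<propagation_fit>\n")
  sl <- x$coefficients[x$coefficients$model == "log_distance" &
                         x$coefficients$term == "log_eff_d", ]
  cat(sprintf("  slope: %.2f RSSI/decade (SE %.2f), n = %d\n",
              sl$estimate, sl$std_error, x$n_used))
  if (length(x$dropped_bins)) {
    cat("  censored bins excluded:",
        paste(x$dropped_bins, collapse = ", "), "m\n")
  }
  invisible(x)
}

#' Distance-bin discriminability
#'
#' For every pair of distance bins in a calibration table, computes a
#' standardized mean difference and a Welch two-sample comparison on
#' orientation-adjusted readings (RSSI residuals after removing the mean
#' orientation effect, mirroring an analysis that includes orientation as
#' a covariate), with multiplicity adjustment across bin pairs. Bin pairs
#' whose adjusted p-value exceeds `alpha` are flagged indistinguishable.
#'
#' @param records Calibration tibble.
#' @param adjust Multiple-comparison adjustment method (see
#'   [stats::p.adjust()]); Holm by default.
#' @param alpha Significance level for the indistinguishability flag.
#' @param min_replicates Bins with fewer readings are excluded (with a
#'   warning).
#' @return A tibble `distance_1`, `distance_2`, `smd`, `statistic`, `df`,
#'   `p_value`, `p_adjusted`, `indistinguishable`.
#' @export
distance_bin_discriminability <- function(records, adjust = "holm",
                                          alpha = 0.05,
                                          min_replicates = 2) {
  counts <- table(records$distance_m)
  small <- as.numeric(names(counts))[counts < min_replicates]
  if (length(small)) {
    warn(paste0("Excluding distance bin(s) with < ", min_replicates,
                " replicates: ", paste(small, collapse = ", ")))
    records <- records[!records$distance_m %in% small, , drop = FALSE]
  }
  bins <- sort(unique(records$distance_m))
  if (length(bins) < 2) abort("Need at least two distance bins.")

  records$resid <- if (length(unique(records$orientation)) > 1) {
    resid(lm(rssi ~ orientation, data = records))
  } else {
    records$rssi - mean(records$rssi)
  }

  pairs <- t(combn(bins, 2))
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    x <- records$resid[records$distance_m == pairs[i, 1]]
    y <- records$resid[records$distance_m == pairs[i, 2]]
    if (sd(x) == 0 && sd(y) == 0) {
      same <- isTRUE(all.equal(mean(x), mean(y)))
      return(tibble::tibble(
        distance_1 = pairs[i, 1], distance_2 = pairs[i, 2],
        smd = if (same) 0 else Inf,
        statistic = if (same) 0 else Inf, df = NA_real_,
        p_value = if (same) 1 else 0
      ))
    }
    tt <- t.test(x, y)
    tibble::tibble(
      distance_1 = pairs[i, 1], distance_2 = pairs[i, 2],
      smd = abs(cohens_d(x, y)),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }) |> purrr::list_rbind()

  rows$p_adjusted <- p.adjust(rows$p_value, method = adjust)
  rows$indistinguishable <- rows$p_adjusted >= alpha
  rows
}

#' Infer a coarse distance bin from a maximum RSSI
#'
#' Maps a log's maximum RSSI to the coarse proximity bin implied by the
#' configured thresholds — at or above the contact threshold: closer than
#' 0.1 m; at or above the social threshold: closer than 5 m; otherwise 5 m
#' or farther. RSSI cannot be inverted into a point distance (orientation
#' and propagation noise are too large), so only the bin and, when a fit
#' is supplied, a per-bin likelihood profile marginalized over orientation
#' are returned.
#'
#' @param max_rssi Integer vector of maximum RSSI values.
#' @param fit Optional [fit_propagation()] result; enables the likelihood
#'   profile.
#' @param thresholds Named thresholds `c(contact = 40, social = 0)`.
#' @return A tibble `max_rssi`, `bin`, and (with a fit) `lik_contact`,
#'   `lik_social`, `lik_far` (normalized per row).
#' @export
infer_distance_bin <- function(max_rssi, fit = NULL,
                               thresholds = c(contact = 40, social = 0)) {
  bin <- dplyr::case_when(
    max_rssi >= thresholds[["contact"]] ~ "<0.1m",
    max_rssi >= thresholds[["social"]] ~ "<5m",
    TRUE ~ ">=5m"
  )
  out <- tibble::tibble(
    max_rssi = max_rssi,
    bin = factor(bin, levels = c("<0.1m", "<5m", ">=5m"))
  )
  if (!is.null(fit)) {
    p <- fit$params
    grids <- list(
      lik_contact = exp(seq(log(p$d_min_clamp), log(0.1), length.out = 25)),
      lik_social = exp(seq(log(0.1), log(5), length.out = 25)),
      lik_far = exp(seq(log(5), log(40), length.out = 25))
    )
    theta <- c(0, pi / 2)
    for (nm in names(grids)) {
      g <- grids[[nm]]
      out[[nm]] <- vapply(max_rssi, function(r) {
        mean(outer(g, theta, function(d, th) {
          dnorm(r, expected_rssi(d, th, "body", p), rssi_noise_sd(d, p))
        }))
      }, numeric(1))
    }
    tot <- out$lik_contact + out$lik_social + out$lik_far
    tot[tot == 0] <- 1
    out$lik_contact <- out$lik_contact / tot
    out$lik_social <- out$lik_social / tot
    out$lik_far <- out$lik_far / tot
  }
  out
}

#' Receiver-station variability
#'
#' Per-station mean RSSI at each tested distance, the coefficient of
#' variation across stations per distance, and multiplicity-adjusted
#' pairwise station comparisons (on readings adjusted for distance and
#' orientation). The CV uses the parallel (station-facing) readings:
#' pooling orientations drives the mean through zero, where a coefficient
#' of variation is meaningless. Station-to-station spread matters because
#' a fixed station bias translates into a distance bias if receivers are
#' used to infer proximity.
#'
#' @param records Tag-receiver calibration tibble (`pair_id` = station).
#' @param adjust Multiple-comparison adjustment method.
#' @return A list with tibbles `per_receiver` (station x distance means),
#'   `cv` (per-distance coefficient of variation of station means), and
#'   `pairwise` (station pair comparisons).
#' @export
receiver_variability <- function(records, adjust = "holm") {
  stations <- sort(unique(records$pair_id))
  if (length(stations) < 2) {
    abort("Coefficient of variation undefined with a single receiver station.")
  }
  par <- records[records$orientation == "parallel", , drop = FALSE]
  if (nrow(par) == 0) par <- records
  per_receiver <- par |>
    dplyr::group_by(receiver_id = .data$pair_id, .data$distance_m) |>
    dplyr::summarise(mean_rssi = mean(.data$rssi), sd_rssi = sd(.data$rssi),
                     n = dplyr::n(), .groups = "drop")

  cv <- per_receiver |>
    dplyr::group_by(.data$distance_m) |>
    dplyr::summarise(
      grand_mean = mean(.data$mean_rssi),
      between_sd = sd(.data$mean_rssi),
      cv = .data$between_sd / abs(.data$grand_mean),
      .groups = "drop"
    )

  records$resid <- resid(lm(rssi ~ factor(distance_m) + orientation,
                            data = records))
  prs <- t(combn(stations, 2))
  pairwise <- purrr::map(seq_len(nrow(prs)), function(i) {
    x <- records$resid[records$pair_id == prs[i, 1]]
    y <- records$resid[records$pair_id == prs[i, 2]]
    tt <- t.test(x, y)
    tibble::tibble(
      receiver_1 = prs[i, 1], receiver_2 = prs[i, 2],
      mean_diff = mean(x) - mean(y),
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  }) |> purrr::list_rbind()
  pairwise$p_adjusted <- p.adjust(pairwise$p_value, method = adjust)
  pairwise$different <- pairwise$p_adjusted < 0.05

  list(per_receiver = per_receiver, cv = cv, pairwise = pairwise)
}
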