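#' Reciprocity of dyadic logs
#'
#' How well do the two tags of a dyad agree? For every dyadic record the
#' absolute between-side difference in maximum, minimum and mean RSSI and
#' in log duration is computed, summarized (mean, SD, range), and a paired
#' mean-difference test on the signed side-a minus side-b values is
#' reported. Perfectly reciprocal logging gives all-zero differences.
#'
#' @param records Record tibble from [call_dyads()].
#' @return A tibble with one row per measure: `measure`, `n`,
#'   `mean_abs_diff`, `sd_abs_diff`, `min_abs_diff`, `max_abs_diff`,
#'   `statistic`, `df`, `p_value`. Warns and returns an empty table when
#'   there are no dyadic records.
#' @export
reciprocity_stats <- function(records) {
  dy <- records[records$status == "dyadic", , drop = FALSE]
  if (nrow(dy) < 2) {
    warn("Fewer than two dyadic records; reciprocity table is empty.")
    return(tibble::tibble(
      measure = character(), n = integer(), mean_abs_diff = numeric(),
      sd_abs_diff = numeric(), min_abs_diff = numeric(),
      max_abs_diff = numeric(), statistic = numeric(), df = numeric(),
      p_value = numeric()
    ))
  }
  measures <- list(
    max_rssi = cbind(dy$max_rssi_a, dy$max_rssi_b),
    min_rssi = cbind(dy$min_rssi_a, dy$min_rssi_b),
    mean_rssi = cbind(dy$mean_rssi_a, dy$mean_rssi_b),
    duration_s = cbind(dy$end_a - dy$start_a, dy$end_b - dy$start_b)
  )
  purrr::imap(measures, function(m, nm) {
    d <- m[, 1] - m[, 2]
    ad <- abs(d)
    tt <- if (sd(d) > 0) t.test(d) else list(statistic = 0, parameter = length(d) - 1,
                                             p.value = 1)
    tibble::tibble(
      measure = nm, n = nrow(m),
      mean_abs_diff = mean(ad), sd_abs_diff = sd(ad),
      min_abs_diff = min(ad), max_abs_diff = max(ad),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }) |> purrr::list_rbind()
}

# Combined per-record RSSI covariates. Two conventions:
# "extremes": max over sides / min over sides — the convention for network
#   weights (an encounter counts by its best evidence of proximity).
# "average": mean of the two sides' statistics — the convention for
#   comparisons against single logs, because taking the min over both
#   sides adds an extra order statistic that single (one-sided) records
#   cannot have. Singles use their own side either way.
record_covariates <- function(records, combine = c("extremes", "average")) {
  combine <- match.arg(combine)
  if (combine == "extremes") {
    out <- dplyr::mutate(records,
      max_rssi = pmax(.data$max_rssi_a, .data$max_rssi_b, na.rm = TRUE),
      min_rssi = pmin(.data$min_rssi_a, .data$min_rssi_b, na.rm = TRUE)
    )
  } else {
    out <- dplyr::mutate(records,
      max_rssi = rowMeans(cbind(.data$max_rssi_a, .data$max_rssi_b),
                          na.rm = TRUE),
      min_rssi = rowMeans(cbind(.data$min_rssi_a, .data$min_rssi_b),
                          na.rm = TRUE)
    )
  }
  dplyr::mutate(out,
    mean_rssi = rowMeans(cbind(.data$mean_rssi_a, .data$mean_rssi_b),
                         na.rm = TRUE),
    spread_rssi = .data$max_rssi - .data$min_rssi
  )
}

#' Model the probability that an encounter is recorded dyadically
#'
#' Logistic regression of record status (dyadic vs single) on encounter
#' covariates, restricted to encounters no longer than `max_duration_s`
#' (the firmware encounter cap), with per-coefficient Wald tests.
#' Dyadic records' covariates average the two sides' statistics so they
#' are comparable with one-sided singles. Encounters with higher minimum
#' RSSI (partners never far apart) and longer duration are expected to be
#' more often dyadic.
#'
#' The full four-predictor model is heavily collinear (min, mean and max
#' RSSI of the same encounter); the `predictors` argument permits fitting
#' the reduced model carrying the informative terms (minimum RSSI and
#' duration).
#'
#' @param records Record tibble from [call_dyads()].
#' @param max_duration_s Keep records with union-span duration at most
#'   this, seconds.
#' @param time_window Optional `c(start, end)`: keep records starting
#'   within this window (e.g. the first hours of logging, before any tag
#'   memory filled).
#' @param predictors Covariates to include, a subset of `"max_rssi"`,
#'   `"min_rssi"`, `"mean_rssi"`, `"duration"`.
#' @return An object of class `dyad_prob_fit` wrapping the [stats::glm()]
#'   fit; supports [tidy()] and [glance()]. Constant predictors are
#'   dropped with a warning; under complete separation a ridge-penalized
#'   fit (glmnet) replaces the unstable ML estimates, with a warning.
#' @export
fit_dyad_probability <- function(records, max_duration_s = 300,
                                 time_window = NULL,
                                 predictors = c("max_rssi", "min_rssi",
                                                "mean_rssi", "duration")) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  dat <- record_covariates(records, combine = "average")
  dat$duration <- dat$duration_s
  dat <- dat[dat$duration <= max_duration_s, , drop = FALSE]
  if (!is.null(time_window)) {
    dat <- dat[dat$start_t >= time_window[1] & dat$start_t <= time_window[2], ,
               drop = FALSE]
  }
  if (nrow(dat) < 10 || length(unique(dat$status)) < 2) {
    abort("Need both dyadic and single records (>= 10 rows) to fit the model.")
  }
  dat$dyadic <- as.integer(dat$status == "dyadic")

  constant <- predictors[vapply(predictors,
                                function(v) sd(dat[[v]]) == 0, logical(1))]
  if (length(constant)) {
    warn(paste0("Dropping constant predictor(s): ",
                paste(constant, collapse = ", ")))
    predictors <- setdiff(predictors, constant)
  }
  form <- stats::reformulate(predictors, response = "dyadic")

  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )

  ridge <- NULL
  if (separated || any(abs(coef(fit)[-1]) > 50, na.rm = TRUE)) {
    separated <- TRUE
    if (requireNamespace("glmnet", quietly = TRUE)) {
      warn("Complete/quasi separation detected; reporting a ridge-penalized fit.")
      x <- as.matrix(dat[predictors])
      ridge <- glmnet::glmnet(x, dat$dyadic, family = "binomial",
                              alpha = 0, lambda = 0.01)
    } else {
      warn("Complete/quasi separation detected; ML estimates are unstable.")
    }
  }

  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"]
  )
  if (!is.null(ridge)) {
    b <- as.numeric(coef(ridge))
    coefs$estimate <- b[match(coefs$term,
                              c("(Intercept)", predictors))]
    coefs$std_error <- NA_real_
    coefs$statistic <- NA_real_
    coefs$p_value <- NA_real_
  }

  structure(list(
    coefficients = coefs,
    glm_fit = fit,
    separated = separated,
    n = nrow(dat),
    n_dyadic = sum(dat$dyadic),
    dropped_predictors = constant
  ), class = "dyad_prob_fit")
}

#' @export
print.dyad_prob_fit <- function(x, ...) {
  cat(sprintf("<dyad_prob_fit> n = %d (%d dyadic)%s\n", x$n, x$n_dyadic,
              if (x$separated) ", separation detected" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Match broken records to unbroken records of similar duration
#'
#' Greedy nearest-duration matching without replacement: broken records
#' (in start-time order) are each paired with the unmatched unbroken
#' dyadic record of most similar duration; equal-duration candidates are
#' resolved in favour of the earlier start. Matching on duration removes
#' the duration confound before comparing RSSI statistics between groups.
#'
#' @param records Record tibble from [call_dyads()] (dyadic records with
#'   `broken` flags), or any tibble with `broken`, `status`,
#'   `duration_s`, `start_t` and `record_id`.
#' @return A tibble of matched pairs: `broken_id`, `unbroken_id`,
#'   `duration_broken`, `duration_unbroken`, `duration_diff`; mean and SD
#'   of `|duration_diff|` as attributes `mean_abs_diff`, `sd_abs_diff`;
#'   unmatched broken records (if unbroken are exhausted) are listed in
#'   `attr(, "unmatched_broken")`.
#' @export
match_broken_logs <- function(records) {
  dy <- records[records$status == "dyadic", , drop = FALSE]
  br <- dy[dy$broken, , drop = FALSE]
  un <- dy[!dy$broken, , drop = FALSE]
  if (nrow(br) < 1 || nrow(un) < 1) {
    abort("Need at least one broken and one unbroken dyadic record.")
  }
  br <- br[order(br$start_t), , drop = FALSE]
  un <- un[order(un$start_t), , drop = FALSE]
  taken <- rep(FALSE, nrow(un))
  rows <- list()
  unmatched <- integer(0)
  for (i in seq_len(nrow(br))) {
    avail <- which(!taken)
    if (!length(avail)) {
      unmatched <- c(unmatched, br$record_id[i])
      next
    }
    dd <- abs(un$duration_s[avail] - br$duration_s[i])
    best <- avail[dd == min(dd)]
    j <- best[which.min(un$start_t[best])]
    taken[j] <- TRUE
    rows[[length(rows) + 1]] <- tibble::tibble(
      broken_id = br$record_id[i], unbroken_id = un$record_id[j],
      duration_broken = br$duration_s[i],
      duration_unbroken = un$duration_s[j],
      duration_diff = br$duration_s[i] - un$duration_s[j]
    )
  }
  out <- purrr::list_rbind(rows)
  attr(out, "mean_abs_diff") <- mean(abs(out$duration_diff))
  attr(out, "sd_abs_diff") <- sd(abs(out$duration_diff))
  attr(out, "unmatched_broken") <- unmatched
  out
}

#' Compare broken and duration-matched unbroken records
#'
#' Per-measure (maximum, minimum, mean RSSI and RSSI spread = max - min)
#' group means for the broken and matched unbroken records, Welch
#' two-sample tests and Cohen's d effect sizes. Broken logs arising from
#' marginal radio contact are expected to show lower RSSI on all three
#' location measures but a similar spread.
#'
#' @param matched Matched-pair tibble from [match_broken_logs()].
#' @param records The record tibble the matching was computed from.
#' @return A tibble `measure`, `mean_broken`, `mean_unbroken`, `diff`,
#'   `statistic`, `df`, `p_value`, `cohens_d`.
#' @export
broken_vs_unbroken_summary <- function(matched, records) {
  if (nrow(matched) < 2) {
    abort("Need at least two matched pairs.")
  }
  cv <- record_covariates(records)
  b <- cv[match(matched$broken_id, cv$record_id), , drop = FALSE]
  u <- cv[match(matched$unbroken_id, cv$record_id), , drop = FALSE]
  measures <- c(max_rssi = "max_rssi", min_rssi = "min_rssi",
                mean_rssi = "mean_rssi", spread_rssi = "spread_rssi")
  purrr::imap(measures, function(col, nm) {
    x <- b[[col]]; y <- u[[col]]
    tt <- if (sd(c(x, y)) > 0) t.test(x, y) else
      list(statistic = 0, parameter = NA_real_, p.value = 1)
    tibble::tibble(
      measure = nm,
      mean_broken = mean(x), mean_unbroken = mean(y),
      diff = mean(x) - mean(y),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      cohens_d = cohens_d(x, y)
    )
  }) |> purrr::list_rbind()
}
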