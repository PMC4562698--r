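# Internal helpers shared across the package.

# Fold an arbitrary heading difference onto [0, pi/2]: antenna orientation is
# axial (a dipole looks the same rotated by pi), so only the acute angle
# between the two antenna axes matters.
fold_angle <- function(theta) {
  a <- abs(theta) %% pi
  pmin(a, pi - a)
}

# Derive a child seed from a global seed and a component label, keeping the
# result a valid 32-bit integer. Gives each pipeline stage an independent,
# reproducible RNG stream.
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

# Integer seconds since epoch -> ISO-8601 UTC string and back.
iso8601 <- function(t, epoch = "2014-08-01 00:00:00") {
  origin <- as.POSIXct(epoch, tz = "UTC")
  format(origin + t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

from_iso8601 <- function(x, epoch = "2014-08-01 00:00:00") {
  origin <- as.POSIXct(epoch, tz = "UTC")
  as.integer(round(as.numeric(
    as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC") - origin,
    units = "secs"
  )))
}

# Parse "HH:MM" clock strings to seconds-of-day; numeric input passes through.
clock_to_seconds <- function(x) {
  if (is.numeric(x)) {
    return(as.integer(x))
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    as.integer(p[1]) * 3600L + as.integer(p[2]) * 60L +
      if (length(p) > 2) as.integer(p[3]) else 0L
  }, integer(1))
}

tag_ids <- function(n) sprintf("T%02d", seq_len(n))
receiver_ids <- function(n) sprintf("R%d", seq_len(n))

is_receiver_id <- function(id) startsWith(id, "R")

# Cohen's d for two independent samples (pooled SD).
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  if (!is.finite(sp) || sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}
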