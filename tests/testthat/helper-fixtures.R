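# Shared builders for small in-memory CDR fixtures.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# One call record row; vectorized over its arguments.
call_rows <- function(ego, times, direction = "outgoing", alter = NULL,
                      duration = 60L, answered = TRUE) {
  times <- ts(times)
  n <- length(times)
  tibble::tibble(
    ego_id = rep_len(ego, n),
    alter_id = if (is.null(alter)) paste0(rep_len(ego, n), "_x") else
      rep_len(alter, n),
    start_time = times,
    direction = rep_len(direction, n),
    duration_s = as.integer(rep_len(duration, n)),
    answered = rep_len(answered, n)
  )
}

make_dataset <- function(..., contacts = NULL, window = NULL) {
  cdr_dataset(dplyr::bind_rows(...), contacts = contacts, window = window)
}

# A one-year window and its three-period partition, reused across tests.
YEAR_WINDOW <- ts(c("2019-01-01 00:00", "2020-01-01 00:00"))
YEAR_PARTITION <- partition_periods(YEAR_WINDOW, 3)

# Probability 24-vector with random support, for distance property tests.
random_prob24 <- function() {
  p <- stats::rexp(24)
  mask <- stats::runif(24) < 0.3
  if (!all(mask)) p[mask] <- 0
  p / sum(p)
}

# Independent oracles, deliberately naive loop implementations.
entropy_oracle <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log2(v)
  h
}

jsd_oracle <- function(p, q) {
  entropy_oracle((p + q) / 2) - (entropy_oracle(p) + entropy_oracle(q)) / 2
}

ks_stat_oracle <- function(x, y) {
  breaks <- sort(unique(c(x, y)))
  d <- 0
  for (b in breaks) {
    d <- max(d, abs(mean(x <= b) - mean(y <= b)))
  }
  d
}
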