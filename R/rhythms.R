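#' Partition an observation window into successive periods
#'
#' Splits a window into `k` contiguous day-aligned intervals of equal day
#' count; when the day count is not divisible by `k`, the earliest periods
#' receive the extra day (366 days, k = 3 gives 122/122/122; 365 gives
#' 122/122/121). Periods are labelled `T1`, `T2`, ...
#'
#' @param window Length-2 POSIXct half-open interval.
#' @param k Number of periods (>= 2 for persistence, >= 1 accepted).
#' @return Tibble `label`, `start`, `end` with half-open rows covering the
#'   window exactly.
#' @export
partition_periods <- function(window, k = 3) {
  stopifnot(k >= 1)
  window <- as.POSIXct(window, tz = "UTC")
  n_days <- as.numeric(difftime(window[2], window[1], units = "days"))
  n_days <- round(n_days)
  if (n_days < k) stop("window shorter than k days", call. = FALSE)
  base <- n_days %/% k
  extra <- n_days %% k
  lens <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
  ends <- window[1] + cumsum(lens) * 86400
  starts <- c(window[1], ends[-k])
  tibble::tibble(label = paste0("T", seq_len(k)), start = starts, end = ends)
}

#' Map timestamps to period labels
#'
#' @param times POSIXct vector.
#' @param partition A [partition_periods()] tibble.
#' @return Character vector of period labels, `NA` outside the partition.
#' @export
period_of <- function(times, partition) {
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(partition))) {
    sel <- times >= partition$start[i] & times < partition$end[i]
    out[sel] <- partition$label[i]
  }
  out
}

#' Map timestamps to six-hour bins of the social day
#'
#' Bins are half-open: night \[00-06), morning \[06-12), afternoon \[12-18),
#' evening \[18-24) local time.
#'
#' @param times POSIXct vector.
#' @return Factor with levels night, morning, afternoon, evening.
#' @export
assign_six_hour_bin <- function(times) {
  h <- lubridate::hour(times)
  factor(SIX_HOUR_BINS[findInterval(h, c(0, 6, 12, 18))],
         levels = SIX_HOUR_BINS)
}

#' Count calls per hour of day
#'
#' Hour slots are half-open `[h, h+1)`, slot 0 being midnight to 1 AM.
#'
#' @param times POSIXct vector of call start times.
#' @return Integer 24-vector of counts; `sum` equals `length(times)`.
#' @export
bin_hourly <- function(times) {
  tabulate(lubridate::hour(times) + 1L, nbins = 24L)
}

#' Turn hourly counts into a call-fraction rhythm
#'
#' The daily rhythm estimator: the fraction of calls falling in each of the
#' 24 one-hour slots, `f(t) = n(t) / sum(n)`. A rhythm with no calls is
#' flagged `empty` and its fractions are `NA` — empty rhythms propagate as
#' missing values, never as zeros.
#'
#' @param counts Integer 24-vector from [bin_hourly()].
#' @param owner Owner label (`ego_id` or `"AGGREGATE"`).
#' @param direction `"outgoing"`, `"incoming"` or `"merged"`.
#' @param period Period label.
#' @return An object of class `hourly_rhythm`.
#' @export
call_fraction <- function(counts, owner = "AGGREGATE",
                          direction = "merged", period = "ALL") {
  stopifnot(length(counts) == 24, all(counts >= 0))
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else rep(NA_real_, 24)
  structure(list(owner = owner, direction = direction, period = period,
                 counts = as.integer(counts), fractions = fractions,
                 total = as.integer(total), empty = total == 0),
            class = "hourly_rhythm")
}

#' @export
print.hourly_rhythm <- function(x, ...) {
  cat("<hourly_rhythm> ", x$owner, " / ", x$direction, " / ", x$period,
      " (", x$total, " calls", if (x$empty) ", EMPTY", ")\n", sep = "")
  invisible(x)
}

subset_calls <- function(dataset, ego = NULL, direction = "merged",
                         period_interval = NULL) {
  calls <- dataset$calls
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(ego)) keep <- keep & calls$ego_id == ego
  if (direction != "merged") keep <- keep & calls$direction == direction
  if (!is.null(period_interval)) {
    keep <- keep & calls$start_time >= period_interval[1] &
      calls$start_time < period_interval[2]
  }
  calls[keep, ]
}

#' Hourly rhythm of one ego
#'
#' @param dataset A [cdr_dataset()].
#' @param ego Ego identifier (must be present).
#' @param direction `"outgoing"`, `"incoming"` or `"merged"` (both pooled).
#' @param period_interval Optional length-2 POSIXct restricting to one
#'   period; `NULL` uses the full window.
#' @param period Label recorded on the result.
#' @return An `hourly_rhythm`.
#' @export
ego_rhythm <- function(dataset, ego, direction = "merged",
                       period_interval = NULL, period = "ALL") {
  if (!ego %in% dataset$calls$ego_id) {
    stop("unknown ego: ", ego, call. = FALSE)
  }
  calls <- subset_calls(dataset, ego, direction, period_interval)
  call_fraction(bin_hourly(calls$start_time), owner = ego,
                direction = direction, period = period)
}

#' Aggregate hourly rhythm of the whole cohort
#'
#' All egos pooled; the aggregate is the count-weighted mean of the ego
#' rhythms.
#'
#' @inheritParams ego_rhythm
#' @return An `hourly_rhythm` with owner `"AGGREGATE"`.
#' @export
aggregate_rhythm <- function(dataset, direction = "merged",
                             period_interval = NULL, period = "ALL") {
  calls <- subset_calls(dataset, NULL, direction, period_interval)
  call_fraction(bin_hourly(calls$start_time), owner = "AGGREGATE",
                direction = direction, period = period)
}

#' Unity-based normalization of a rhythm
#'
#' Rescales the 24 fractions to the (0, 1) range,
#' `(p - min(p)) / (max(p) - min(p))`, for comparable heat-map rows. A
#' constant rhythm has no shape to rescale (the formula is 0/0); it maps to
#' all zeros with the `"constant"` attribute set so downstream rendering
#' stays honest.
#'
#' @param rhythm An `hourly_rhythm` (not empty).
#' @return Numeric 24-vector in `[0, 1]` with min 0 and max 1 unless the
#'   input was constant.
#' @export
normalize_unity <- function(rhythm) {
  stopifnot(inherits(rhythm, "hourly_rhythm"))
  if (rhythm$empty) stop("cannot normalize an empty rhythm", call. = FALSE)
  p <- rhythm$fractions
  rng <- range(p)
  if (diff(rng) == 0) {
    return(structure(rep(0, 24), constant = TRUE))
  }
  structure((p - rng[1]) / (rng[2] - rng[1]), constant = FALSE)
}

#' Per-ego rhythm table
#'
#' One row per (ego, direction, period) with the 24 hourly fractions in
#' wide columns `h00` ... `h23`, the layout used for rhythm heat maps.
#'
#' @param dataset A [cdr_dataset()].
#' @param partition Optional [partition_periods()] tibble; `NULL` gives the
#'   full-window rhythms only.
#' @param directions Directions to tabulate.
#' @param normalized If `TRUE`, rows are unity-normalized (constant or
#'   empty rows become `NA`).
#' @return Tibble with identifying columns, `n_calls`, and `h00`..`h23`.
#' @export
rhythm_table <- function(dataset, partition = NULL,
                         directions = c("outgoing", "incoming"),
                         normalized = FALSE) {
  periods <- if (is.null(partition)) {
    tibble::tibble(label = "ALL", start = dataset$window[1],
                   end = dataset$window[2])
  } else {
    partition
  }
  rows <- list()
  for (e in egos_of(dataset)) {
    for (d in directions) {
      for (i in seq_len(nrow(periods))) {
        r <- ego_rhythm(dataset, e, d,
                        period_interval = c(periods$start[i], periods$end[i]),
                        period = periods$label[i])
        vals <- if (r$empty) {
          rep(NA_real_, 24)
        } else if (normalized) {
          nv <- normalize_unity(r)
          if (isTRUE(attr(nv, "constant"))) rep(NA_real_, 24) else as.numeric(nv)
        } else {
          r$fractions
        }
        names(vals) <- sprintf("h%02d", 0:23)
        rows[[length(rows) + 1]] <- tibble::tibble(
          ego_id = e, direction = d, period = periods$label[i],
          n_calls = r$total, !!!as.list(vals)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
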