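#' Select the densest 12-month observation window
#'
#' Participants enroll at different dates, so the analysis window is chosen
#' as the fixed-length interval (day granularity) during which the greatest
#' number of egos were actively participating — an ego counts for a
#' candidate window when it has at least one call in every calendar month
#' of that window, so partially enrolled egos do not pull the window onto
#' their silent months. Ties break to the earliest start.
#'
#' @param dataset A [cdr_dataset()].
#' @param months Window length in calendar months (default 12).
#' @return Length-2 POSIXct half-open interval `[start, end)`.
#' @export
select_window <- function(dataset, months = 12) {
  stopifnot(inherits(dataset, "cdr_dataset"), nrow(dataset$calls) > 0)
  days <- lubridate::floor_date(dataset$calls$start_time, "day")
  span_start <- min(days)
  span_end <- max(days)
  if (span_start %m+% months(months) > span_end + lubridate::days(1)) {
    shortfall <- as.numeric(difftime(span_start %m+% months(months),
                                     span_end + lubridate::days(1),
                                     units = "days"))
    stop(sprintf(
      "dataset spans less than %d months: %d more day(s) of data needed",
      months, ceiling(shortfall)), call. = FALSE)
  }
  cand <- sort(unique(days))
  cand <- cand[cand %m+% months(months) <= span_end + lubridate::days(1)]
  if (length(cand) == 0) cand <- span_start
  ego <- dataset$calls$ego_id
  best_n <- -1L
  best_start <- cand[1]
  for (i in seq_along(cand)) {
    bounds <- cand[i] %m+% months(0:months)
    slice <- findInterval(days, bounds)
    inside <- slice >= 1 & slice <= months
    covered <- tapply(slice[inside], ego[inside],
                      function(x) dplyr::n_distinct(x) == months)
    n <- sum(covered)
    if (n > best_n) {
      best_n <- n
      best_start <- cand[i]
    }
  }
  as.POSIXct(c(best_start, best_start %m+% months(months)), tz = "UTC")
}

#' @importFrom lubridate %m+% %m-%
NULL

#' Restrict a dataset to a window
#'
#' Keeps the records with `start_time` in the half-open window and sets the
#' dataset window accordingly.
#'
#' @param dataset A [cdr_dataset()].
#' @param window Length-2 POSIXct `[start, end)`.
#' @return A [cdr_dataset()].
#' @export
clip_to_window <- function(dataset, window) {
  keep <- dataset$calls$start_time >= window[1] &
    dataset$calls$start_time < window[2]
  cdr_dataset(dataset$calls[keep, ], dataset$contacts, window = window)
}

#' Drop unanswered incoming calls
#'
#' Unanswered incoming calls say nothing about when the ego chooses to
#' communicate, so only answered incoming calls enter the analysis;
#' outgoing calls are untouched. Idempotent.
#'
#' @param dataset A [cdr_dataset()].
#' @return A [cdr_dataset()].
#' @export
filter_answered <- function(dataset) {
  keep <- dataset$calls$direction == "outgoing" | dataset$calls$answered
  cdr_dataset(dataset$calls[keep, ], dataset$contacts, dataset$window)
}

#' Keep egos active throughout the observation period
#'
#' "Active throughout" means at least one call in each period of the
#' partition; with `both_directions = TRUE` (default) at least one outgoing
#' AND one incoming call per period, since an empty per-period distribution
#' would leave the persistence self-distance undefined for that direction.
#' The excluded egos are attached as the `"excluded_egos"` attribute.
#'
#' @param dataset A [cdr_dataset()].
#' @param partition A [partition_periods()] tibble covering the window.
#' @param both_directions Require activity in both call directions per
#'   period (default `TRUE`) or in either direction.
#' @return A [cdr_dataset()] restricted to the retained egos.
#' @export
filter_active_egos <- function(dataset, partition, both_directions = TRUE) {
  calls <- dataset$calls
  egos <- egos_of(dataset)
  per <- period_of(calls$start_time, partition)
  active <- vapply(egos, function(e) {
    idx <- calls$ego_id == e
    all(vapply(partition$label, function(p) {
      in_p <- idx & !is.na(per) & per == p
      if (both_directions) {
        any(calls$direction[in_p] == "outgoing") &&
          any(calls$direction[in_p] == "incoming")
      } else {
        any(in_p)
      }
    }, logical(1)))
  }, logical(1))
  retained <- egos[active]
  out <- cdr_dataset(calls[calls$ego_id %in% retained, ],
                     dataset$contacts, dataset$window)
  attr(out, "excluded_egos") <- egos[!active]
  out
}

#' Summarize cohort structure
#'
#' Per-direction totals and per-ego call-count quartiles, the audit table
#' reported before and after preprocessing. Quartiles use the
#' linear-interpolation definition (`stats::quantile` type 7).
#'
#' @param dataset A [cdr_dataset()].
#' @return Tibble with one row per direction: `direction`, `n_egos`,
#'   `total_calls`, `q1`, `median`, `q3`.
#' @export
cohort_summary <- function(dataset) {
  calls <- dataset$calls
  egos <- egos_of(dataset)
  purrr_map <- function(d) {
    n_per_ego <- vapply(egos, function(e) {
      sum(calls$ego_id == e & calls$direction == d)
    }, numeric(1))
    qs <- stats::quantile(n_per_ego, c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
    tibble::tibble(direction = d, n_egos = length(egos),
                   total_calls = sum(n_per_ego),
                   q1 = qs[1], median = qs[2], q3 = qs[3])
  }
  dplyr::bind_rows(lapply(DIRECTIONS, purrr_map))
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: select the densest window, clip, drop unanswered incoming
#' calls, then keep egos active in every period. Returns the filtered
#' dataset plus before/after summaries and the excluded-ego list.
#'
#' @param dataset A [cdr_dataset()].
#' @param months Window length in months.
#' @param k Number of periods for the activity filter.
#' @param both_directions Passed to [filter_active_egos()].
#' @return List: `dataset`, `partition`, `excluded_egos`,
#'   `summary_before`, `summary_after`.
#' @export
preprocess_cdr <- function(dataset, months = 12, k = 3,
                           both_directions = TRUE) {
  window <- select_window(dataset, months = months)
  clipped <- clip_to_window(dataset, window)
  summary_before <- cohort_summary(clipped)
  answered <- filter_answered(clipped)
  partition <- partition_periods(window, k = k)
  active <- filter_active_egos(answered, partition,
                               both_directions = both_directions)
  list(dataset = active,
       partition = partition,
       excluded_egos = attr(active, "excluded_egos"),
       summary_before = summary_before,
       summary_after = cohort_summary(active))
}
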