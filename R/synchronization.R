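#' Synchronization of outgoing and incoming rhythms
#'
#' For each ego and each period, a two-sample Kolmogorov-Smirnov comparison
#' of the times of day of outgoing versus incoming calls, under the null
#' that the two directions follow the same law. Raw p-values are
#' Holm-Sidak adjusted over the whole family (egos x periods; 63 tests for
#' a 21-ego, 3-period cohort). An ego is synchronized when every adjusted
#' per-period p-value exceeds 0.05. Ego-periods with an empty side are
#' marked missing and drop out of the family.
#'
#' @param dataset A preprocessed [cdr_dataset()].
#' @param partition A [partition_periods()] tibble.
#' @param ks_input `"times"` (fractional hours) or `"hours"`.
#' @param alpha Significance level for the synchronized flag.
#' @return List of class `sync_result`: `tests` (ego x period rows with
#'   `statistic`, `p_value`, `p_adjusted`), `egos` (per-ego `synchronized`
#'   flag and 12-month `out_in_d`), `family_size`.
#' @export
run_synchronization <- function(dataset, partition,
                                ks_input = c("times", "hours"),
                                alpha = 0.05) {
  ks_input <- match.arg(ks_input)
  rows <- list()
  for (e in egos_of(dataset)) {
    for (i in seq_len(nrow(partition))) {
      iv <- c(partition$start[i], partition$end[i])
      out <- time_of_day_hours(subset_calls(dataset, e, "outgoing", iv)$start_time)
      inc <- time_of_day_hours(subset_calls(dataset, e, "incoming", iv)$start_time)
      if (ks_input == "hours") {
        out <- floor(out)
        inc <- floor(inc)
      }
      if (length(out) == 0 || length(inc) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          ego_id = e, period = partition$label[i],
          n_out = length(out), n_in = length(inc),
          statistic = NA_real_, p_value = NA_real_)
      } else {
        kt <- ks_two_sample(out, inc)
        rows[[length(rows) + 1]] <- tibble::tibble(
          ego_id = e, period = partition$label[i],
          n_out = length(out), n_in = length(inc),
          statistic = kt$statistic, p_value = kt$p_value)
      }
    }
  }
  tests <- dplyr::bind_rows(rows)
  tests$p_adjusted <- NA_real_
  ok <- !is.na(tests$p_value)
  tests$p_adjusted[ok] <- holm_sidak(tests$p_value[ok])

  egos <- tests |>
    dplyr::group_by(.data$ego_id) |>
    dplyr::summarise(
      n_missing = sum(is.na(.data$p_value)),
      synchronized = all(.data$p_adjusted > alpha, na.rm = TRUE) &
        any(!is.na(.data$p_adjusted)),
      .groups = "drop")
  egos$out_in_d <- unname(vapply(egos$ego_id, function(e) {
    tryCatch(out_in_distance(dataset, e), error = function(err) NA_real_)
  }, numeric(1)))
  structure(list(tests = tests, egos = egos, family_size = sum(ok),
                 alpha = alpha),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat("<sync_result> ", sum(x$egos$synchronized), "/", nrow(x$egos),
      " egos synchronized (family size ", x$family_size, ", alpha ",
      x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Distance between an ego's outgoing and incoming daily rhythms
#'
#' Square-root Jensen-Shannon distance between the ego's 12-month outgoing
#' and incoming 24-bin call-fraction rhythms; symmetric in the direction
#' labels.
#'
#' @param dataset A [cdr_dataset()].
#' @param ego Ego identifier.
#' @return Distance in `[0, 1]`.
#' @export
out_in_distance <- function(dataset, ego) {
  r_out <- ego_rhythm(dataset, ego, "outgoing")
  r_in <- ego_rhythm(dataset, ego, "incoming")
  if (r_out$empty || r_in$empty) {
    stop("ego ", ego, " has an empty direction over the window",
         call. = FALSE)
  }
  sqrt_jsd(r_out$fractions, r_in$fractions)
}

#' Persistence of the merged (direction-free) rhythm
#'
#' Convenience wrapper: pools outgoing and incoming calls and runs the
#' persistence analysis on the merged stream.
#'
#' @inheritParams run_persistence
#' @return A `persistence_result`.
#' @export
merged_persistence <- function(dataset, partition,
                               metric = c("sqrt_jsd", "l2"),
                               ks_input = c("times", "hours")) {
  run_persistence(dataset, partition, direction = "merged",
                  metric = metric, ks_input = ks_input)
}
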