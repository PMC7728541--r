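time_of_day_hours <- function(times) {
  lubridate::hour(times) + lubridate::minute(times) / 60 +
    lubridate::second(times) / 3600
}

# Per-ego, per-period call-fraction rhythms for one direction.
# Returns a list: egos -> list(periods -> hourly_rhythm).
period_rhythms <- function(dataset, partition, direction = "merged") {
  egos <- egos_of(dataset)
  stats::setNames(lapply(egos, function(e) {
    stats::setNames(lapply(seq_len(nrow(partition)), function(i) {
      ego_rhythm(dataset, e, direction,
                 period_interval = c(partition$start[i], partition$end[i]),
                 period = partition$label[i])
    }), partition$label)
  }), egos)
}

#' Self-distance of an ego's rhythm across successive periods
#'
#' `D_self(T)` is the distance between the ego's daily rhythms in periods
#' `T` and `T+1`; the mean is taken over the successive pairs (one fewer
#' than the number of periods). Set `denominator = "periods"` to divide
#' the pair sum by the period count instead.
#'
#' @param rhythms List of `hourly_rhythm` objects, one per period, in
#'   period order; at least two, none empty.
#' @param metric `"sqrt_jsd"` or `"l2"`.
#' @param denominator `"pairs"` (default) or `"periods"`.
#' @return List: `pairs` tibble (`from`, `to`, `d`), `mean_d_self`.
#' @export
d_self <- function(rhythms, metric = c("sqrt_jsd", "l2"),
                   denominator = c("pairs", "periods")) {
  metric <- match.arg(metric)
  denominator <- match.arg(denominator)
  stopifnot(length(rhythms) >= 2)
  if (any(vapply(rhythms, function(r) r$empty, logical(1)))) {
    stop("ego has an empty per-period rhythm; excluded from persistence",
         call. = FALSE)
  }
  n <- length(rhythms)
  d <- vapply(seq_len(n - 1), function(i) {
    rhythm_distance(rhythms[[i]]$fractions, rhythms[[i + 1]]$fractions,
                    metric)
  }, numeric(1))
  denom <- if (denominator == "pairs") n - 1 else n
  list(pairs = tibble::tibble(
         from = vapply(rhythms[-n], function(r) r$period, character(1)),
         to = vapply(rhythms[-1], function(r) r$period, character(1)),
         d = d),
       mean_d_self = sum(d) / denom)
}

#' Reference distance of an ego against the rest of the cohort
#'
#' For each period, the distance between the ego's rhythm and every other
#' ego's rhythm in the same period; the mean runs over all (other ego,
#' period) combinations — 60 values for a 21-ego, 3-period cohort. Pairs
#' where either side is empty are skipped.
#'
#' @param ego Ego identifier.
#' @param all_rhythms Output of the internal per-cohort rhythm builder, a
#'   list egos -> periods -> `hourly_rhythm` (as built inside
#'   [run_persistence()]).
#' @param metric `"sqrt_jsd"` or `"l2"`.
#' @return List: `values` numeric vector, `mean_d_ref`.
#' @export
d_ref <- function(ego, all_rhythms, metric = c("sqrt_jsd", "l2")) {
  metric <- match.arg(metric)
  others <- setdiff(names(all_rhythms), ego)
  stopifnot(length(others) >= 1)
  mine <- all_rhythms[[ego]]
  vals <- c()
  for (p in names(mine)) {
    if (mine[[p]]$empty) next
    for (o in others) {
      r <- all_rhythms[[o]][[p]]
      if (r$empty) next
      vals <- c(vals, rhythm_distance(mine[[p]]$fractions, r$fractions,
                                      metric))
    }
  }
  list(values = vals, mean_d_ref = mean(vals))
}

#' Persistence criterion
#'
#' An ego's daily rhythm is persistent if and only if the mean
#' self-distance is strictly below the mean reference distance,
#' `<D_self> / <D_ref> < 1`.
#'
#' @param mean_d_self,mean_d_ref Non-negative reals; `mean_d_ref` must be
#'   positive for the ratio to be defined.
#' @return Logical.
#' @export
persistence_flag <- function(mean_d_self, mean_d_ref) {
  stopifnot(mean_d_ref > 0)
  mean_d_self / mean_d_ref < 1
}

#' Persistence analysis of daily rhythms over a cohort
#'
#' For every ego: the distances between its rhythms in successive periods
#' (`D_self`), the distances to every other ego's rhythm in the same
#' period (`D_ref`), the persistence flag `<D_self>/<D_ref> < 1`, and a
#' nonparametric confirmation — a two-sample Kolmogorov-Smirnov comparison
#' of the raw call times-of-day between successive periods, Holm-Sidak
#' adjusted over the whole family (egos x successive pairs). Egos with an
#' empty per-period rhythm are excluded with a reason.
#'
#' @param dataset A preprocessed [cdr_dataset()].
#' @param partition A [partition_periods()] tibble.
#' @param direction `"outgoing"`, `"incoming"` or `"merged"`.
#' @param metric `"sqrt_jsd"` (default) or `"l2"`.
#' @param ks_input `"times"` (default; time-of-day in fractional hours,
#'   mitigating ties) or `"hours"` (integer hour of day).
#' @param denominator Passed to [d_self()].
#' @return List of class `persistence_result`: `results` tibble (one row
#'   per retained ego), `ks` tibble (one row per ego x successive pair),
#'   `excluded` tibble, plus `direction`, `metric`, `family_size`.
#' @export
run_persistence <- function(dataset, partition,
                            direction = c("outgoing", "incoming", "merged"),
                            metric = c("sqrt_jsd", "l2"),
                            ks_input = c("times", "hours"),
                            denominator = c("pairs", "periods")) {
  direction <- match.arg(direction)
  metric <- match.arg(metric)
  ks_input <- match.arg(ks_input)
  denominator <- match.arg(denominator)
  stopifnot(nrow(partition) >= 2)

  rhythms <- period_rhythms(dataset, partition, direction)
  usable <- vapply(rhythms, function(rr) {
    !any(vapply(rr, function(r) r$empty, logical(1)))
  }, logical(1))
  excluded <- tibble::tibble(
    ego_id = names(rhythms)[!usable],
    reason = "empty per-period rhythm"
  )
  rhythms_ok <- rhythms[usable]
  if (length(rhythms_ok) < 2) {
    stop("persistence needs at least two egos with complete period rhythms",
         call. = FALSE)
  }

  res_rows <- list()
  ks_rows <- list()
  for (e in names(rhythms_ok)) {
    ds <- d_self(rhythms_ok[[e]], metric, denominator)
    dr <- d_ref(e, rhythms_ok, metric)
    row <- tibble::tibble(ego_id = e, direction = direction, metric = metric,
                          mean_d_self = ds$mean_d_self,
                          mean_d_ref = dr$mean_d_ref,
                          n_ref = length(dr$values),
                          persistent = persistence_flag(ds$mean_d_self,
                                                        dr$mean_d_ref))
    for (i in seq_len(nrow(ds$pairs))) {
      row[[paste0("d_self_", ds$pairs$from[i], ds$pairs$to[i])]] <- ds$pairs$d[i]
    }
    res_rows[[e]] <- row

    # KS confirmation on raw times of day between successive periods
    for (i in seq_len(nrow(partition) - 1)) {
      a <- subset_calls(dataset, e, direction,
                        c(partition$start[i], partition$end[i]))
      b <- subset_calls(dataset, e, direction,
                        c(partition$start[i + 1], partition$end[i + 1]))
      x <- time_of_day_hours(a$start_time)
      y <- time_of_day_hours(b$start_time)
      if (ks_input == "hours") {
        x <- floor(x)
        y <- floor(y)
      }
      kt <- ks_two_sample(x, y)
      ks_rows[[length(ks_rows) + 1]] <- tibble::tibble(
        ego_id = e,
        comparison = paste0(partition$label[i], "_vs_", partition$label[i + 1]),
        statistic = kt$statistic, p_value = kt$p_value)
    }
  }
  ks <- dplyr::bind_rows(ks_rows)
  ks$p_adjusted <- holm_sidak(ks$p_value)
  structure(list(results = dplyr::bind_rows(res_rows), ks = ks,
                 excluded = excluded, direction = direction, metric = metric,
                 family_size = nrow(ks)),
            class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  n <- nrow(x$results)
  cat("<persistence_result> ", x$direction, " / ", x$metric, ": ",
      sum(x$results$persistent), "/", n, " egos persistent; ",
      "KS family size ", x$family_size, "\n", sep = "")
  invisible(x)
}
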