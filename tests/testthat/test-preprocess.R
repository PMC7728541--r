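# Brute-force window scan: every call day as candidate start, counting
# egos with a call in every month-slice of the window; earliest argmax.
window_oracle <- function(calls, months = 12) {
  days <- lubridate::floor_date(calls$start_time, "day")
  cand <- sort(unique(days))
  best <- cand[1]; best_n <- -1
  for (ci in seq_along(cand)) {
    s <- cand[ci]
    e <- s %m+% months(months)
    if (e > max(days) + lubridate::days(1)) next
    n <- 0
    for (ego in unique(calls$ego_id)) {
      dd <- days[calls$ego_id == ego]
      full <- TRUE
      for (m in seq_len(months)) {
        lo <- s %m+% months(m - 1)
        hi <- s %m+% months(m)
        if (!any(dd >= lo & dd < hi)) { full <- FALSE; break }
      }
      if (full) n <- n + 1
    }
    if (n > best_n) { best_n <- n; best <- s }
  }
  best
}

monthly_calls <- function(ego, from, n_months) {
  times <- ts(from) %m+% months(seq_len(n_months) - 1)
  call_rows(ego, format(times, "%Y-%m-%d 10:00"))
}

test_that("the densest 12-month window is selected, ties to the earliest start", {
  # all egos active over the same 13 months
  d <- make_dataset(monthly_calls("A", "2019-01-05", 13),
                    monthly_calls("B", "2019-01-20", 13))
  w <- select_window(d)
  expect_equal(w[1], ts("2019-01-05"))

  # staggered enrollment: A months 1-14, B months 3-15, C months 3-14
  d <- make_dataset(monthly_calls("A", "2019-01-10", 14),
                    monthly_calls("B", "2019-03-10", 13),
                    monthly_calls("C", "2019-03-10", 12))
  w <- select_window(d)
  expect_equal(w[1], window_oracle(d$calls))
  expect_equal(w[1], ts("2019-03-10"))

  # single ego: anchored at the first call date
  d <- make_dataset(monthly_calls("A", "2019-02-14", 13))
  expect_equal(select_window(d)[1], ts("2019-02-14"))
})

test_that("a dataset shorter than the window length is an error naming the shortfall", {
  d <- make_dataset(monthly_calls("A", "2019-01-01", 6))
  expect_error(select_window(d), "less than 12 months")
})

test_that("unanswered incoming calls are dropped, outgoing untouched, idempotently", {
  d <- make_dataset(
    call_rows("e1", sprintf("2019-01-0%d 10:00", 1:5), "incoming",
              answered = c(TRUE, TRUE, FALSE, TRUE, FALSE)),
    call_rows("e1", sprintf("2019-02-0%d 10:00", 1:3), "outgoing"))
  f <- filter_answered(d)
  expect_equal(sum(f$calls$direction == "incoming"), 3)
  expect_equal(sum(f$calls$direction == "outgoing"), 3)
  expect_identical(filter_answered(f)$calls, f$calls)

  all_ans <- make_dataset(call_rows("e1", "2019-01-01 10:00", "incoming"))
  expect_equal(nrow(filter_answered(all_ans)$calls), 1)

  none <- make_dataset(
    call_rows("e1", "2019-01-01 10:00", "incoming", answered = FALSE),
    call_rows("e1", "2019-01-02 10:00", "outgoing"))
  expect_equal(filter_answered(none)$calls$direction, "outgoing")
})

test_that("egos must be active in both directions in every period to be retained", {
  both <- function(ego, from, n) {
    dplyr::bind_rows(monthly_calls(ego, from, n),
                     dplyr::mutate(monthly_calls(ego, from, n),
                                   direction = "incoming"))
  }
  d <- make_dataset(
    both("full", "2019-01-15", 12),
    both("silentT3", "2019-01-15", 8),                       # nothing in T3
    dplyr::bind_rows(monthly_calls("noInT2", "2019-01-15", 12),
                     dplyr::mutate(monthly_calls("noInT2", "2019-01-15", 4),
                                   direction = "incoming"),
                     dplyr::mutate(monthly_calls("noInT2", "2019-09-15", 4),
                                   direction = "incoming")),
    window = YEAR_WINDOW)
  f <- filter_active_egos(d, YEAR_PARTITION)
  expect_equal(egos_of(f), "full")
  expect_setequal(attr(f, "excluded_egos"), c("silentT3", "noInT2"))
  # retained + excluded partition the original ego set
  expect_setequal(c(egos_of(f), attr(f, "excluded_egos")), egos_of(d))

  # either-direction relaxation keeps the ego missing one direction
  f2 <- filter_active_egos(d, YEAR_PARTITION, both_directions = FALSE)
  expect_true("noInT2" %in% egos_of(f2))
  # idempotence
  expect_identical(filter_active_egos(f, YEAR_PARTITION)$calls, f$calls)
})

test_that("cohort summaries report exact totals and interpolated quartiles", {
  d <- make_dataset(call_rows("e1", sprintf("2019-01-0%d 09:00", 1:4)))
  s <- cohort_summary(d)
  expect_equal(s$total_calls[s$direction == "outgoing"], 4)
  expect_equal(s$median[s$direction == "outgoing"], 4)

  d3 <- make_dataset(call_rows("e1", "2019-01-01 09:00"),
                     call_rows("e2", c("2019-01-01 09:00", "2019-01-02 09:00")),
                     call_rows("e3", sprintf("2019-01-0%d 09:00", 1:3)))
  s3 <- cohort_summary(d3)
  expect_equal(s3$median[s3$direction == "outgoing"], 2)
  expect_equal(s3$total_calls[s3$direction == "outgoing"], 6)
})

test_that("preprocessing never increases any summary count", {
  sim <- simulate_calls(synthetic_config(n_egos = 4, months = 12, seed = 3,
                                         n_silent = 1,
                                         unanswered_incoming = 0.2))
  before <- cohort_summary(sim$dataset)
  prep <- preprocess_cdr(sim$dataset)
  after <- cohort_summary(prep$dataset)
  for (d in before$direction) {
    expect_lte(after$total_calls[after$direction == d],
               before$total_calls[before$direction == d])
  }
  expect_setequal(c(egos_of(prep$dataset), prep$excluded_egos),
                  egos_of(sim$dataset))
})
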