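alter_calls <- function(ego, alters, hour = 10, direction = "outgoing") {
  times <- sprintf("2019-01-%02d %02d:00", seq_along(alters), hour)
  call_rows(ego, times, direction, alter = alters)
}

test_that("origin entropy measures the alter mix of a time bin in bits", {
  d <- make_dataset(alter_calls("e1", rep("a1", 5)), window = YEAR_WINDOW)
  expect_equal(origin_entropy(d, "e1", "morning"), 0)

  d4 <- make_dataset(alter_calls("e1", rep(c("a1", "a2", "a3", "a4"), 2)),
                     window = YEAR_WINDOW)
  expect_equal(origin_entropy(d4, "e1", "morning"), 2)  # log2(4)

  d31 <- make_dataset(alter_calls("e1", c("a1", "a1", "a1", "b")),
                      window = YEAR_WINDOW)
  expect_equal(origin_entropy(d31, "e1", "morning"), 0.811278,
               tolerance = 1e-6)
  expect_true(is.na(origin_entropy(d31, "e1", "night")))
  # bounded by log2 of the alter count
  expect_lte(origin_entropy(d31, "e1", "morning"), log2(2))
})

test_that("origin entropy is invariant under duplicating every record", {
  d <- make_dataset(alter_calls("e1", c("a1", "a1", "a2", "a3")),
                    window = YEAR_WINDOW)
  doubled <- cdr_dataset(dplyr::bind_rows(d$calls, d$calls),
                         window = d$window)
  expect_equal(origin_entropy(doubled, "e1", "morning"),
               origin_entropy(d, "e1", "morning"))
})

test_that("relative entropy handles the degenerate reference cases", {
  expect_equal(relative_entropy(1.3, 1.3), 1)
  expect_equal(relative_entropy(0, 0.5), 0)
  expect_true(is.na(relative_entropy(0.5, 0)))
  expect_true(is.na(relative_entropy(NA, 1)))
})

test_that("block shuffling permutes times but preserves the multiset and per-alter counts", {
  sim <- simulate_calls(synthetic_config(n_egos = 1, months = 3,
                                         n_periods = 3, seed = 17))
  d <- sim$dataset
  e <- egos_of(d)[1]
  orig <- d$calls[d$calls$direction == "outgoing", ]
  for (s in 1:20) {
    sh <- shuffle_times(d, e, "outgoing", seed = s)
    got <- sh$calls[sh$calls$direction == "outgoing", ]
    # timestamp multiset preserved overall and per 14-day block
    expect_equal(sort(got$start_time), sort(orig$start_time))
    blk <- function(x) floor(as.numeric(difftime(x, d$window[1],
                                                 units = "days")) / 14)
    expect_equal(table(blk(got$start_time)), table(blk(orig$start_time)))
    # per-alter call counts preserved exactly
    expect_equal(table(got$alter_id), table(orig$alter_id))
    # the untouched direction is bitwise identical
    expect_equal(sh$calls[sh$calls$direction == "incoming", ],
                 d$calls[d$calls$direction == "incoming", ])
  }
  one <- make_dataset(call_rows("e9", "2019-05-01 10:00"))
  expect_equal(shuffle_times(one, "e9", seed = 1)$calls, one$calls)
})

test_that("reference entropy is zero for a single alter and reproducible under a seed", {
  d <- make_dataset(
    call_rows("e1", sprintf("2019-%02d-10 10:00", 1:12), alter = "onlyone"),
    window = YEAR_WINDOW)
  h <- reference_entropy(d, "e1", "morning", "T1", YEAR_PARTITION,
                         direction = "outgoing", iterations = 10, seed = 3)
  expect_equal(as.numeric(h), 0)

  sim <- simulate_calls(synthetic_config(n_egos = 1, months = 12, seed = 19))
  a <- reference_entropy(sim$dataset, "ego01", "evening", "T2",
                         YEAR_PARTITION, "outgoing", iterations = 5, seed = 42)
  b <- reference_entropy(sim$dataset, "ego01", "evening", "T2",
                         YEAR_PARTITION, "outgoing", iterations = 5, seed = 42)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_length(attr(a, "replicates"), 5)
})

test_that("time-independent alter choice calibrates the relative entropy near one", {
  sim <- simulate_calls(synthetic_config(n_egos = 4, months = 12, seed = 23,
                                         evening_concentration = 1))
  prep <- preprocess_cdr(sim$dataset)
  ent <- entropy_profile(prep$dataset, prep$partition, iterations = 100,
                         seed = 9)
  ok <- !is.na(ent$h_rel) & ent$n_calls >= 20
  expect_gt(sum(ok), 10)
  expect_gt(mean(ent$h_rel[ok]), 0.93)
  expect_lt(mean(ent$h_rel[ok]), 1.07)
  expect_true(all(ent$low_support == (ent$n_calls < 5)))
})

test_that("top-2 alter profiles rank by count with duration then ID tie-breaks", {
  d <- make_dataset(alter_calls("e1", c("a1", "a1", "a2", "a2", "a3")),
                    window = YEAR_WINDOW)
  pr <- top2_profile(d, "e1", "outgoing")
  expect_equal(pr$top_alters, c("a1", "a2"))
  expect_equal(pr$bins$fraction[pr$bins$bin == "morning"], 4 / 5)
  expect_true(is.na(pr$bins$fraction[pr$bins$bin == "night"]))

  # exactly two alters: fraction 1 in every non-empty bin
  d2 <- make_dataset(alter_calls("e1", c("a1", "a2", "a1")),
                     window = YEAR_WINDOW)
  pr2 <- top2_profile(d2, "e1", "outgoing")
  expect_equal(pr2$bins$fraction[pr2$bins$bin == "morning"], 1)

  # single alter: degenerate top set of size 1
  d1 <- make_dataset(alter_calls("e1", rep("solo", 3)), window = YEAR_WINDOW)
  pr1 <- top2_profile(d1, "e1", "outgoing")
  expect_equal(pr1$top_alters, "solo")
  expect_equal(pr1$bins$fraction[pr1$bins$bin == "morning"], 1)

  # tie on counts broken by larger total duration
  dt <- make_dataset(
    call_rows("e1", c("2019-01-01 10:00", "2019-01-02 10:00"),
              alter = c("short", "long"), duration = c(10L, 500L)),
    call_rows("e1", "2019-01-03 10:00", alter = "top", duration = 60L),
    call_rows("e1", "2019-01-04 10:00", alter = "top", duration = 60L))
  expect_equal(top2_profile(dt, "e1", "outgoing")$top_alters,
               c("top", "long"))
})

test_that("duration profiles average by category and bin with exact aggregation", {
  contacts <- tibble::tibble(ego_id = "e1", alter_id = c("mum", "doc"),
                             category = c("family", "health_professional"))
  d <- make_dataset(
    call_rows("e1", "2019-01-01 08:00", alter = "mum", duration = 600L),
    call_rows("e1", "2019-01-01 09:00", alter = "doc", duration = 100L),
    call_rows("e1", "2019-01-01 19:00", alter = "mum", duration = 300L),
    call_rows("e1", "2019-01-01 20:00", alter = "stranger", duration = 42L),
    contacts = contacts)
  dp <- duration_profile(d)
  expect_equal(dp$mean_duration_s[dp$category == "family" &
                                    dp$bin == "morning"], 600)
  # uncategorized alters fall into "other"
  expect_equal(dp$mean_duration_s[dp$category == "other" &
                                    dp$bin == "evening"], 42)
  # count-weighted bin means aggregate to the pooled category mean
  fam <- dp[dp$category == "family", ]
  expect_equal(sum(fam$mean_duration_s * fam$n_calls) / sum(fam$n_calls),
               mean(c(600, 300)))
})
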