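# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

entropy_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  c_pos <- counts[counts > 0]
  log2(n) - sum(c_pos * log2(c_pos)) / n
}

#' Origin entropy of an ego's alter distribution
#'
#' Shannon entropy (base 2) of the distribution of call counts over the
#' ego's alters, restricted to one direction, period, and six-hour bin:
#' `H = -sum_k p_k log2 p_k` where `p_k` is the fraction of those calls
#' placed to (received from) alter `k`. Zero means every call involved a
#' single alter; `log2(m)` is the maximum for `m` alters. `NA` when the
#' bin holds no calls.
#'
#' @param dataset A [cdr_dataset()].
#' @param ego Ego identifier.
#' @param bin One of `"night"`, `"morning"`, `"afternoon"`, `"evening"`.
#' @param direction `"outgoing"`, `"incoming"` or `"merged"`.
#' @param period_interval Optional length-2 POSIXct period restriction.
#' @return Entropy in bits, or `NA` for an empty bin.
#' @export
origin_entropy <- function(dataset, ego, bin, direction = "merged",
                           period_interval = NULL) {
  stopifnot(bin %in% SIX_HOUR_BINS)
  calls <- subset_calls(dataset, ego, direction, period_interval)
  calls <- calls[assign_six_hour_bin(calls$start_time) == bin, ]
  if (nrow(calls) == 0) return(NA_real_)
  entropy_from_counts(as.integer(table(calls$alter_id)))
}

#' Relative entropy of alter specificity
#'
#' The origin entropy normalized by the mean reference entropy from the
#' shuffle null. Values near 1 mean the alter mix in that time bin looks
#' like the time-randomized null; values tending to 0 mean calls in that
#' bin concentrate on specific alters. Missing when the reference entropy
#' is numerically zero (the ratio is undefined) or either input is `NA`.
#'
#' @param h_orig Origin entropy in bits.
#' @param mean_h_ref Mean reference entropy in bits.
#' @param tol Threshold below which the reference is treated as zero.
#' @return Dimensionless ratio, or `NA`.
#' @export
relative_entropy <- function(h_orig, mean_h_ref, tol = 1e-9) {
  ifelse(is.na(h_orig) | is.na(mean_h_ref) | mean_h_ref < tol,
         NA_real_, h_orig / mean_h_ref)
}

#' Shuffle call times within two-week blocks
#'
#' The null model for alter specificity: within each consecutive 14-day
#' block of the window, the timestamps of the ego's calls (one direction)
#' are randomly permuted across that block's records, leaving alter
#' labels, durations, and the answered flag attached to their records.
#' This preserves exactly, per block, the timestamp multiset, the
#' per-alter call counts, and the total call count — only the pairing of
#' alters to times is randomized. A trailing block shorter than
#' `block_days` is shuffled as-is.
#'
#' @param dataset A [cdr_dataset()].
#' @param ego Ego identifier.
#' @param direction `"outgoing"`, `"incoming"` or `"merged"`.
#' @param block_days Shuffle-block length in days (default 14).
#' @param seed Optional integer seed for reproducibility.
#' @return A [cdr_dataset()] with the selected stream's times permuted.
#' @export
shuffle_times <- function(dataset, ego, direction = "merged",
                          block_days = 14, seed = NULL) {
  calls <- dataset$calls
  sel <- calls$ego_id == ego
  if (direction != "merged") sel <- sel & calls$direction == direction
  idx <- which(sel)
  if (length(idx) > 1) {
    block <- floor(as.numeric(difftime(calls$start_time[idx],
                                       dataset$window[1],
                                       units = "days")) / block_days)
    with_seed(seed, {
      for (ids in split(seq_along(idx), block)) {
        if (length(ids) > 1) {
          calls$start_time[idx[ids]] <-
            calls$start_time[idx[ids]][sample.int(length(ids))]
        }
      }
    })
  }
  cdr_dataset(calls, dataset$contacts, dataset$window)
}

# Vectorized shuffle-null engine for one ego x direction stream.
# Returns a matrix iterations x n_slots of origin entropies, where slots
# enumerate (period, six-hour bin) cells.
shuffled_entropy_matrix <- function(times, alters, window_start, partition,
                                    iterations, block_days = 14) {
  np <- nrow(partition)
  n_slots <- np * 4L
  per_idx <- match(period_of(times, partition), partition$label)
  bin_idx <- as.integer(assign_six_hour_bin(times))
  keep <- !is.na(per_idx)
  per_idx <- per_idx[keep]
  bin_idx <- bin_idx[keep]
  times <- times[keep]
  alters <- alters[keep]
  slot <- (per_idx - 1L) * 4L + bin_idx
  alter_idx <- as.integer(factor(alters))
  n_alter <- max(alter_idx, 0L)
  block <- floor(as.numeric(difftime(times, window_start,
                                     units = "days")) / block_days)
  by_block <- split(seq_along(slot), block)

  out <- matrix(NA_real_, iterations, n_slots)
  for (it in seq_len(iterations)) {
    slot_sh <- slot
    for (ids in by_block) {
      if (length(ids) > 1) slot_sh[ids] <- slot[ids][sample.int(length(ids))]
    }
    counts <- tabulate(slot_sh + n_slots * (alter_idx - 1L),
                       nbins = n_slots * n_alter)
    cmat <- matrix(counts, n_slots, n_alter)
    n_per_slot <- rowSums(cmat)
    clog <- cmat * log2(pmax(cmat, 1))
    h <- ifelse(n_per_slot > 0,
                log2(pmax(n_per_slot, 1)) - rowSums(clog) / pmax(n_per_slot, 1),
                NA_real_)
    out[it, ] <- h
  }
  colnames(out) <- paste(rep(partition$label, each = 4),
                         rep(SIX_HOUR_BINS, np), sep = ".")
  out
}

#' Reference entropy under the shuffle null
#'
#' Mean origin entropy of one (ego, direction, period, bin) cell across
#' `iterations` independent two-week-block shuffles of the ego's call
#' times. The per-replicate values are attached as the `"replicates"`
#' attribute for diagnostics. Deterministic given `seed`.
#'
#' @inheritParams origin_entropy
#' @param partition A [partition_periods()] tibble.
#' @param period Period label within the partition.
#' @param iterations Number of shuffle replicates (>= 1; 1000 in the
#'   standard analysis).
#' @param seed Integer seed.
#' @param block_days Shuffle-block length in days.
#' @return Mean reference entropy in bits (`NA` if the cell never holds a
#'   call), with attribute `"replicates"`.
#' @export
reference_entropy <- function(dataset, ego, bin, period, partition,
                              direction = "merged", iterations = 1000,
                              seed = NULL, block_days = 14) {
  stopifnot(iterations >= 1, bin %in% SIX_HOUR_BINS,
            period %in% partition$label)
  calls <- subset_calls(dataset, ego, direction, NULL)
  reps <- with_seed(seed, {
    m <- shuffled_entropy_matrix(calls$start_time, calls$alter_id,
                                 dataset$window[1], partition,
                                 iterations, block_days)
    m[, paste(period, bin, sep = ".")]
  })
  v <- if (all(is.na(reps))) NA_real_ else mean(reps, na.rm = TRUE)
  structure(v, replicates = reps)
}

#' Alter-specificity entropy table for a cohort
#'
#' For every (ego, direction, period, six-hour bin): the origin entropy,
#' the mean reference entropy over `iterations` two-week-block shuffles,
#' and their ratio (the relative entropy). All bins of an ego x direction
#' stream share the same shuffle replicates, as the null permutes the
#' whole stream at once. Cells with fewer than `min_calls` calls are kept
#' but flagged `low_support` — nocturnal bins are typically too sparse to
#' interpret.
#'
#' @param dataset A preprocessed [cdr_dataset()].
#' @param partition A [partition_periods()] tibble.
#' @param directions Directions to analyze.
#' @param iterations Shuffle replicates (default 1000).
#' @param seed Integer seed driving all shuffles.
#' @param block_days Shuffle-block length in days.
#' @param min_calls Support threshold for the `low_support` flag.
#' @return Tibble: `ego_id`, `direction`, `period`, `bin`, `n_calls`,
#'   `n_alters`, `h_orig`, `mean_h_ref`, `h_rel`, `low_support`.
#' @export
entropy_profile <- function(dataset, partition,
                            directions = c("outgoing", "incoming"),
                            iterations = 1000, seed = NULL,
                            block_days = 14, min_calls = 5) {
  rows <- list()
  with_seed(seed, {
    for (e in egos_of(dataset)) {
      for (d in directions) {
        calls <- subset_calls(dataset, e, d, NULL)
        per_idx <- match(period_of(calls$start_time, partition),
                         partition$label)
        bin_idx <- as.integer(assign_six_hour_bin(calls$start_time))
        ref <- shuffled_entropy_matrix(calls$start_time, calls$alter_id,
                                       dataset$window[1], partition,
                                       iterations, block_days)
        mean_ref <- colMeans(ref, na.rm = TRUE)
        mean_ref[is.nan(mean_ref)] <- NA_real_
        for (p in seq_len(nrow(partition))) {
          for (b in seq_along(SIX_HOUR_BINS)) {
            in_cell <- !is.na(per_idx) & per_idx == p & bin_idx == b
            n <- sum(in_cell)
            h_o <- if (n > 0) {
              entropy_from_counts(as.integer(table(calls$alter_id[in_cell])))
            } else NA_real_
            m_ref <- mean_ref[(p - 1) * 4 + b]
            rows[[length(rows) + 1]] <- tibble::tibble(
              ego_id = e, direction = d, period = partition$label[p],
              bin = SIX_HOUR_BINS[b], n_calls = n,
              n_alters = dplyr::n_distinct(calls$alter_id[in_cell]),
              h_orig = h_o, mean_h_ref = unname(m_ref),
              h_rel = relative_entropy(h_o, unname(m_ref)),
              low_support = n < min_calls)
          }
        }
      }
    }
  })
  dplyr::bind_rows(rows)
}

#' Fraction of calls with the two most-contacted alters
#'
#' Ranks the ego's alters by call count over the full window for one
#' direction (ties broken by larger total duration, then lexicographic
#' alter ID) and reports, per six-hour bin, the fraction of calls
#' involving the top two.
#'
#' @param dataset A [cdr_dataset()].
#' @param ego Ego identifier (must have at least one call in scope).
#' @param direction `"outgoing"`, `"incoming"` or `"merged"` (pools both
#'   directions for the ranking and the fractions).
#' @return List: `top_alters` (1 or 2 IDs), `bins` tibble (`bin`,
#'   `n_calls`, `fraction`; fraction `NA` in empty bins).
#' @export
top2_profile <- function(dataset, ego, direction = "merged") {
  calls <- subset_calls(dataset, ego, direction, NULL)
  if (nrow(calls) == 0) {
    stop("ego ", ego, " has no calls for direction ", direction,
         call. = FALSE)
  }
  ranking <- calls |>
    dplyr::group_by(.data$alter_id) |>
    dplyr::summarise(n = dplyr::n(),
                     total_duration = sum(.data$duration_s),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), dplyr::desc(.data$total_duration),
                   .data$alter_id)
  top <- head(ranking$alter_id, 2)
  bin <- assign_six_hour_bin(calls$start_time)
  bins <- tibble::tibble(bin = SIX_HOUR_BINS)
  bins$n_calls <- unname(vapply(SIX_HOUR_BINS,
                                function(b) sum(bin == b), numeric(1)))
  bins$fraction <- unname(vapply(SIX_HOUR_BINS, function(b) {
    n <- sum(bin == b)
    if (n == 0) NA_real_ else sum(bin == b & calls$alter_id %in% top) / n
  }, numeric(1)))
  list(top_alters = top, bins = bins)
}

#' Mean call duration by social category and time of day
#'
#' Joins each call to the alter's social category from the contact
#' directory (alters absent from the directory fall into `"other"`) and
#' reports the mean call duration per category per six-hour bin, plus an
#' hourly breakdown. Count-weighted bin means aggregate exactly to the
#' pooled category mean.
#'
#' @param dataset A [cdr_dataset()].
#' @param contacts Contact directory tibble; defaults to the dataset's.
#' @return Tibble: `category`, `bin`, `n_calls`, `mean_duration_s`.
#' @export
duration_profile <- function(dataset, contacts = NULL) {
  if (is.null(contacts)) contacts <- dataset$contacts
  calls <- dataset$calls |>
    dplyr::left_join(contacts[, c("ego_id", "alter_id", "category")],
                     by = c("ego_id", "alter_id")) |>
    dplyr::mutate(category = dplyr::coalesce(.data$category, "other"),
                  bin = assign_six_hour_bin(.data$start_time))
  calls |>
    dplyr::group_by(.data$category, .data$bin) |>
    dplyr::summarise(n_calls = dplyr::n(),
                     mean_duration_s = mean(.data$duration_s),
                     .groups = "drop") |>
    dplyr::arrange(.data$category, .data$bin)
}
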