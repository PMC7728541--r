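#' CSV dialect options for call-detail-record tables
#'
#' French provider exports commonly use semicolon delimiters and day-first
#' dates; the canonical schema is comma-separated with ISO 8601 timestamps.
#'
#' @param delim Field delimiter, `","` (default) or `";"`.
#' @param dayfirst Logical; if `TRUE`, ambiguous dates are parsed day-first
#'   (`31/01/2019 10:05`). ISO 8601 timestamps parse either way.
#' @return A list of class `cdr_dialect`.
#' @export
cdr_dialect <- function(delim = ",", dayfirst = FALSE) {
  stopifnot(delim %in% c(",", ";"), is.logical(dayfirst))
  structure(list(delim = delim, dayfirst = dayfirst), class = "cdr_dialect")
}

#' Construct a call-detail-record dataset
#'
#' Bundles a call table, a contact directory, and a half-open observation
#' window into one validated object. Records are sorted by ego and start
#' time. Timestamps are local wall-clock values; no timezone arithmetic is
#' performed (they are stored as UTC so that arithmetic follows the clock
#' face, daylight-saving transitions taken at face value).
#'
#' @param calls Tibble with columns `ego_id`, `alter_id`, `start_time`
#'   (POSIXct), `direction` (`"outgoing"`/`"incoming"`), `duration_s`
#'   (non-negative integer seconds), `answered` (logical; always `TRUE`
#'   for outgoing calls).
#' @param contacts Tibble with columns `ego_id`, `alter_id`, `category`,
#'   or `NULL` for an empty directory.
#' @param window Length-2 POSIXct, half-open `[start, end)`. Defaults to
#'   the day-aligned hull of the call times.
#' @return An object of class `cdr_dataset`: a list with elements `calls`,
#'   `contacts`, `window`.
#' @export
cdr_dataset <- function(calls, contacts = NULL, window = NULL) {
  calls <- tibble::as_tibble(calls)
  required <- c("ego_id", "alter_id", "start_time", "direction",
                "duration_s", "answered")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0) {
    stop("calls table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  calls$ego_id <- as.character(calls$ego_id)
  calls$alter_id <- as.character(calls$alter_id)
  calls$direction <- as.character(calls$direction)
  calls$duration_s <- as.integer(calls$duration_s)
  calls$answered <- as.logical(calls$answered)
  if (!inherits(calls$start_time, "POSIXct")) {
    stop("start_time must be POSIXct", call. = FALSE)
  }
  attr(calls$start_time, "tzone") <- "UTC"
  if (nrow(calls) > 0) {
    stopifnot(all(calls$direction %in% DIRECTIONS),
              all(calls$duration_s >= 0),
              all(calls$ego_id != calls$alter_id))
  }
  calls <- dplyr::arrange(calls, .data$ego_id, .data$start_time)

  if (is.null(contacts)) {
    contacts <- tibble::tibble(ego_id = character(), alter_id = character(),
                               category = character())
  }
  contacts <- tibble::as_tibble(contacts)
  stopifnot(all(c("ego_id", "alter_id", "category") %in% names(contacts)))

  if (is.null(window)) {
    if (nrow(calls) == 0) {
      window <- as.POSIXct(c("1970-01-01", "1970-01-02"), tz = "UTC")
    } else {
      window <- c(
        lubridate::floor_date(min(calls$start_time), "day"),
        lubridate::ceiling_date(max(calls$start_time) + 1, "day")
      )
    }
  }
  window <- as.POSIXct(window, tz = "UTC")
  stopifnot(length(window) == 2, window[1] < window[2])
  if (nrow(calls) > 0 &&
      (min(calls$start_time) < window[1] || max(calls$start_time) >= window[2])) {
    stop("call start_time outside the observation window", call. = FALSE)
  }

  structure(list(calls = calls, contacts = contacts, window = window),
            class = "cdr_dataset")
}

#' @export
print.cdr_dataset <- function(x, ...) {
  cat("<cdr_dataset>\n")
  cat("  calls:   ", nrow(x$calls), " records, ",
      dplyr::n_distinct(x$calls$ego_id), " egos\n", sep = "")
  cat("  contacts:", nrow(x$contacts), "directory entries\n")
  cat("  window:  [", format(x$window[1], "%Y-%m-%d"), ", ",
      format(x$window[2], "%Y-%m-%d"), ")\n", sep = "")
  invisible(x)
}

egos_of <- function(dataset) sort(unique(dataset$calls$ego_id))

parse_cdr_times <- function(x, dayfirst = FALSE) {
  orders <- if (dayfirst) {
    c("dmY HM", "dmY HMS", "Ymd HM", "Ymd HMS")
  } else {
    c("Ymd HM", "Ymd HMS", "dmY HM", "dmY HMS")
  }
  suppressWarnings(lubridate::parse_date_time(x, orders = orders, tz = "UTC"))
}

#' Read a call table from a delimited file
#'
#' Expects a header naming the six canonical fields `ego_id`, `alter_id`,
#' `start_time`, `direction`, `duration_s`, `answered`. Rows that violate
#' record invariants (unparseable timestamp, negative or non-numeric
#' duration, unknown direction token, ego calling itself) are rejected
#' individually with a reason, not fatal; the rejected rows are attached as
#' the `"rejected"` attribute and their count as `"n_rejected"`.
#'
#' @param path Path to the calls CSV.
#' @param contacts Optional contact directory tibble (see [read_contacts()]).
#' @param dialect A [cdr_dialect()].
#' @param window Optional observation window passed to [cdr_dataset()].
#' @return A [cdr_dataset()] with rejection bookkeeping attached to `$calls`.
#' @export
read_calls <- function(path, contacts = NULL, dialect = cdr_dialect(),
                       window = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  required <- c("ego_id", "alter_id", "start_time", "direction",
                "duration_s", "answered")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  ts <- parse_cdr_times(raw$start_time, dialect$dayfirst)
  dur <- suppressWarnings(as.numeric(raw$duration_s))
  dir_ok <- tolower(raw$direction) %in% DIRECTIONS
  ans <- tolower(raw$answered) %in% c("true", "t", "1", "yes")

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(dur) | dur < 0 | dur != floor(dur)] <- "invalid duration"
  reason[!dir_ok] <- "unknown direction"
  reason[raw$ego_id == raw$alter_id] <- "ego equals alter"
  keep <- is.na(reason)

  calls <- tibble::tibble(
    ego_id = raw$ego_id[keep],
    alter_id = raw$alter_id[keep],
    start_time = ts[keep],
    direction = tolower(raw$direction[keep]),
    duration_s = as.integer(dur[keep]),
    answered = ans[keep]
  )
  dataset <- cdr_dataset(calls, contacts = contacts, window = window)
  rejected <- dplyr::mutate(raw[!keep, ], reason = reason[!keep])
  attr(dataset$calls, "rejected") <- rejected
  attr(dataset$calls, "n_rejected") <- nrow(rejected)
  dataset
}

#' Read a contact directory
#'
#' One row per (ego, alter) pair with a social-category label. Duplicate
#' keys resolve last-wins; the number of overwritten rows is recorded in the
#' `"n_duplicates"` attribute. Labels outside the questionnaire vocabulary
#' (family, friend, acquaintance, health_professional, other) are kept
#' verbatim and marked `canonical = FALSE` — real directories carry
#' free-text labels such as "associations".
#'
#' @param path Path to the contacts CSV.
#' @param dialect A [cdr_dialect()].
#' @return Tibble `ego_id`, `alter_id`, `category`, `canonical`.
#' @export
read_contacts <- function(path, dialect = cdr_dialect()) {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  stopifnot(all(c("ego_id", "alter_id", "category") %in% names(raw)))
  n_before <- nrow(raw)
  out <- raw |>
    dplyr::group_by(.data$ego_id, .data$alter_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(canonical = .data$category %in% CANONICAL_CATEGORIES) |>
    dplyr::arrange(.data$ego_id, .data$alter_id)
  n_dup <- n_before - nrow(out)
  if (n_dup > 0) {
    warning(n_dup, " duplicate (ego, alter) row(s) resolved last-wins",
            call. = FALSE)
  }
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Write a call table in the canonical schema
#'
#' Deterministic column order and ISO 8601 minute-precision timestamps, so
#' that `read_calls(write_calls(D))` round-trips field for field.
#'
#' @param dataset A [cdr_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(dataset, path) {
  stopifnot(inherits(dataset, "cdr_dataset"))
  out <- dataset$calls |>
    dplyr::mutate(start_time = format(.data$start_time, "%Y-%m-%dT%H:%M"),
                  answered = ifelse(.data$answered, "true", "false")) |>
    dplyr::select("ego_id", "alter_id", "start_time", "direction",
                  "duration_s", "answered")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a contact directory in the canonical schema
#'
#' @param contacts Contact directory tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  readr::write_csv(contacts[, c("ego_id", "alter_id", "category")], path,
                   progress = FALSE)
  invisible(path)
}
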