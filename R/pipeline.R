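#' Run the full circadian CDR analysis pipeline
#'
#' Orchestrates preprocessing, rhythm estimation, persistence,
#' synchronization, and alter-specificity from one configuration, writing
#' every stage's table plus run metadata to an output directory. Any stage
#' failure aborts with the stage name; tables already written are kept.
#'
#' @param calls Path to a calls CSV (see [read_calls()]).
#' @param contacts Path to a contacts CSV (see [read_contacts()]).
#' @param out_dir Output directory (created if needed).
#' @param window_months Observation-window length in months.
#' @param n_periods Number of successive periods.
#' @param metric `"sqrt_jsd"` or `"l2"`.
#' @param ks_input `"times"` or `"hours"`.
#' @param iterations Shuffle replicates for the entropy null.
#' @param seed Integer seed for the shuffle null.
#' @param min_calls Low-support threshold for entropy cells.
#' @param dialect A [cdr_dialect()].
#' @return Invisibly, a list with every stage result and the metadata.
#' @export
run_pipeline <- function(calls, contacts, out_dir,
                         window_months = 12, n_periods = 3,
                         metric = c("sqrt_jsd", "l2"),
                         ks_input = c("times", "hours"),
                         iterations = 1000, seed = 1, min_calls = 5,
                         dialect = cdr_dialect()) {
  metric <- match.arg(metric)
  ks_input <- match.arg(ks_input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  io <- stage("cdr_io", {
    if (!file.exists(contacts)) stop("contacts file not found: ", contacts)
    dir_tab <- read_contacts(contacts, dialect)
    read_calls(calls, contacts = dir_tab, dialect = dialect)
  })

  prep <- stage("preprocess", preprocess_cdr(io, months = window_months,
                                             k = n_periods))
  cohort <- prep$dataset
  write_calls(cohort, file.path(out_dir, "calls_filtered.csv"))
  readr::write_csv(tibble::tibble(ego_id = prep$excluded_egos),
                   file.path(out_dir, "excluded_egos.csv"), progress = FALSE)
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(prep$summary_before, stage = "before"),
    dplyr::mutate(prep$summary_after, stage = "after")),
    file.path(out_dir, "summary.csv"), progress = FALSE)

  rh <- stage("rhythms", rhythm_table(cohort, prep$partition))
  readr::write_csv(rh, file.path(out_dir, "rhythms.csv"), progress = FALSE)

  pers <- list()
  for (d in c("outgoing", "incoming", "merged")) {
    pers[[d]] <- stage("persistence",
                       run_persistence(cohort, prep$partition, d,
                                       metric = metric, ks_input = ks_input))
  }
  pers_tab <- dplyr::bind_rows(lapply(pers, function(x) x$results))
  readr::write_csv(pers_tab, file.path(out_dir, "persistence.csv"),
                   progress = FALSE)
  readr::write_csv(
    dplyr::bind_rows(lapply(names(pers), function(d) {
      dplyr::mutate(pers[[d]]$ks, direction = d)
    })), file.path(out_dir, "persistence_ks.csv"), progress = FALSE)

  sync <- stage("synchronization",
                run_synchronization(cohort, prep$partition,
                                    ks_input = ks_input))
  readr::write_csv(sync$tests, file.path(out_dir, "sync_tests.csv"),
                   progress = FALSE)
  readr::write_csv(sync$egos, file.path(out_dir, "sync_egos.csv"),
                   progress = FALSE)

  ent <- stage("alter_specificity",
               entropy_profile(cohort, prep$partition,
                               iterations = iterations, seed = seed,
                               min_calls = min_calls))
  readr::write_csv(ent, file.path(out_dir, "entropy.csv"), progress = FALSE)

  top2 <- stage("alter_specificity", dplyr::bind_rows(lapply(
    egos_of(cohort), function(e) {
      dplyr::bind_rows(lapply(c("outgoing", "incoming"), function(d) {
        pr <- tryCatch(top2_profile(cohort, e, d), error = function(err) NULL)
        if (is.null(pr)) return(NULL)
        dplyr::mutate(pr$bins, ego_id = e, direction = d,
                      top_alters = paste(pr$top_alters, collapse = ";"))
      }))
    })))
  readr::write_csv(top2, file.path(out_dir, "top2.csv"), progress = FALSE)

  dur <- stage("alter_specificity", duration_profile(cohort))
  readr::write_csv(dur, file.path(out_dir, "durations.csv"),
                   progress = FALSE)

  meta <- list(
    package_version = as.character(utils::packageVersion("cdrhythms")),
    seed = seed, metric = metric, ks_input = ks_input,
    iterations = iterations, window_months = window_months,
    n_periods = n_periods,
    window = format(cohort$window, "%Y-%m-%dT%H:%M"),
    n_egos_before = dplyr::n_distinct(io$calls$ego_id),
    n_egos_after = length(egos_of(cohort)),
    excluded_egos = prep$excluded_egos,
    # The multiple-comparison families actually used; recorded because
    # family definitions are a common source of ambiguity.
    ks_families = list(
      persistence = lapply(pers, function(x) x$family_size),
      synchronization = sync$family_size,
      synchronization_alternative_pairs =
        dplyr::n_distinct(sync$tests$ego_id) * (n_periods - 1)
    ),
    n_persistent = lapply(pers, function(x) sum(x$results$persistent)),
    n_synchronized = sum(sync$egos$synchronized)
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  summary_tab <- pers_tab |>
    dplyr::select("ego_id", "direction", "persistent") |>
    tidyr::pivot_wider(names_from = "direction", values_from = "persistent",
                       names_prefix = "persistent_") |>
    dplyr::left_join(sync$egos[, c("ego_id", "synchronized", "out_in_d")],
                     by = "ego_id")
  readr::write_csv(summary_tab, file.path(out_dir, "ego_summary.csv"),
                   progress = FALSE)

  invisible(list(preprocess = prep, rhythms = rh, persistence = pers,
                 synchronization = sync, entropy = ent, top2 = top2,
                 durations = dur, metadata = meta,
                 ego_summary = summary_tab))
}
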