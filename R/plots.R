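#' Heat map of per-ego daily rhythms
#'
#' Egos by hour-of-day tiles of unity-normalized call fractions, one facet
#' per direction; missing (empty or constant) rhythms render gray.
#'
#' @param dataset A [cdr_dataset()].
#' @param partition Optional [partition_periods()] tibble; `NULL` plots
#'   full-window rhythms.
#' @return A ggplot object.
#' @export
plot_rhythm_heatmap <- function(dataset, partition = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tab <- rhythm_table(dataset, partition, normalized = TRUE) |>
    tidyr::pivot_longer(dplyr::starts_with("h"), names_to = "hour",
                        values_to = "fraction") |>
    dplyr::mutate(hour = as.integer(sub("^h", "", .data$hour)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$hour, y = .data$ego_id,
                                    fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(period ~ direction) +
    ggplot2::scale_fill_viridis_c(na.value = "grey70",
                                  name = "normalized\nfraction") +
    ggplot2::labs(x = "hour of day", y = NULL)
}
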