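#' Plot the 50-bin gaze time course
#'
#' Famous vs mean-unknown proportion of gaze per 100-ms bin over the
#' 5,000-ms parallel display, averaged over participants when several
#' time courses are stacked.
#'
#' @param tc A [timecourse()] tibble, optionally with extra grouping
#'   columns (e.g. `participant_id`).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc) {
  avg <- tc |>
    group_by(.data$bin, .data$t_start) |>
    summarise(famous = mean(.data$famous), unknown = mean(.data$unknown),
              .groups = "drop") |>
    tidyr::pivot_longer(c("famous", "unknown"), names_to = "face_type",
                        values_to = "proportion")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$t_start + 50,
                                    y = .data$proportion,
                                    color = .data$face_type)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(200, 1000), linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "Time from display onset (ms)",
                  y = "Proportion of gaze time",
                  color = "Face type") +
    ggplot2::theme_minimal()
}

#' Plot preference indices by phase (and group)
#'
#' Bar summary of the mean preference index per phase with standard
#' errors over participants.
#'
#' @param indices Stacked [preference_index()] rows, optionally with a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_preference_index <- function(indices) {
  grouping <- intersect(c("group", "phase"), names(indices))
  summ <- indices |>
    group_by(across(dplyr::all_of(grouping))) |>
    summarise(mean_index = mean(.data$index),
              sem = sd(.data$index) / sqrt(n()), .groups = "drop") |>
    mutate(phase = factor(.data$phase, labels = paste("Phase",
                                                      sort(unique(.data$phase)))))
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$phase,
                                          y = .data$mean_index)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_index - .data$sem,
                                        ymax = .data$mean_index + .data$sem),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Preference index") +
    ggplot2::theme_minimal()
  if ("group" %in% grouping) {
    p <- p + ggplot2::facet_wrap(~group)
  }
  p
}

#' Plot classification metrics against their chance baseline
#'
#' @param metrics Main metric rows (e.g. [within_participant_classify()]
#'   output stacked over participants).
#' @param baseline Optional [random_tag_baseline()] rows.
#' @return A ggplot object.
#' @export
plot_classification_metrics <- function(metrics, baseline = NULL) {
  long <- bind_rows(metrics, baseline) |>
    tidyr::pivot_longer(c("roc_auc", "balanced_accuracy", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$analysis, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, fill = "grey90") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
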