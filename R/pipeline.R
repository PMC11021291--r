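#' Run the full STM-CIT analysis pipeline
#'
#' Executes every stage end to end on synthetic data: schedule
#' generation, gaze simulation for one or more participant groups, event
#' detection, feature extraction, inferential statistics on the
#' preference indices, within-participant classification with its
#' random-tag baseline, and (optionally) between-participant
#' classification; writes all stage outputs, a run manifest and a
#' markdown report under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stage derives its own substream via
#'   [substream_seed()].
#' @param groups Named list of [gaze_config()] objects, one per
#'   participant group.
#' @param n_participants Participants per group.
#' @param geometry A [screen_geometry()].
#' @param clf_config A [classification_config()].
#' @param strict Strict misidentification exclusions.
#' @param between Also run the leave-one-participant-out analysis.
#' @return Invisibly, a list with all in-memory results (`schedule`,
#'   `indices`, `features`, `timecourses`, `location_tests`, `anova`,
#'   `posthoc`, `metrics`, `baseline`, `comparison`, `manifest`).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         groups = list(control = gaze_config()),
                         n_participants = 15,
                         geometry = screen_geometry(),
                         clf_config = classification_config(),
                         strict = FALSE, between = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) inform(paste0("[stmcit] stage: ", name))

  stage("design")
  schedule <- generate_schedule(cit_faces(), seed = substream_seed(seed, "design"))
  write_schedule_json(schedule, file.path(out_dir, "schedule.json"))
  write_schedule_csv(schedule, file.path(out_dir, "schedule.csv"))

  indices <- list()
  features <- list()
  timecourses <- list()
  single <- list()
  analyses <- list()
  for (g in names(groups)) {
    stage(paste0("simulate+detect+features: ", g))
    cohort <- simulate_cohort(schedule, groups[[g]], n_participants,
                              seed = substream_seed(seed, g),
                              geometry = geometry)
    ana <- analyze_cohort(cohort, schedule, geometry, strict = strict,
                          include_timecourse = TRUE)
    analyses[[g]] <- ana
    indices[[g]] <- mutate(ana$indices, group = g, .before = 1)
    features[[g]] <- mutate(ana$features, group = g, .before = 1)
    single[[g]] <- mutate(ana$single, group = g, .before = 1)
    timecourses[[g]] <- purrr::map_dfr(ana$participants, function(a) {
      mutate(a$timecourse, participant_id = a$participant_id, group = g,
             .before = 1)
    })
  }
  indices <- bind_rows(indices)
  features <- bind_rows(features)
  single <- bind_rows(single)
  timecourses <- bind_rows(timecourses)
  utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(single, file.path(out_dir, "single_face_measures.csv"),
                   row.names = FALSE)
  utils::write.csv(timecourses, file.path(out_dir, "timecourse.csv"),
                   row.names = FALSE)

  stage("stats")
  loc <- indices |>
    group_by(.data$group, .data$phase) |>
    summarise(location_test(.data$index), .groups = "drop")
  anova_res <- NULL
  posthoc <- NULL
  if (length(groups) >= 2) {
    anova_res <- mixed_anova(indices)
    posthoc <- tukey_posthoc(anova_res)
  }

  stage("classify")
  pg_ids <- unique(paste(features$group, features$participant_id))
  metrics <- purrr::map_dfr(seq_along(pg_ids), function(i) {
    rows <- filter(features,
                   paste(.data$group, .data$participant_id) == pg_ids[i])
    within_participant_classify(
      rows, clf_config, seed = substream_seed(seed, "classify", i),
      participant_id = pg_ids[i]
    )
  })
  baseline <- purrr::map_dfr(names(groups), function(g) {
    rows <- filter(features, .data$group == g) |>
      mutate(participant_id = paste(g, .data$participant_id))
    random_tag_baseline(rows, clf_config,
                        seed = substream_seed(seed, "baseline-grp",
                                              match(g, names(groups))))
  })
  comparison <- compare_to_baseline(metrics, baseline)
  between_metrics <- NULL
  if (between) {
    between_metrics <- purrr::map_dfr(names(groups), function(g) {
      rows <- filter(features, .data$group == g) |>
        mutate(participant_id = paste(g, .data$participant_id))
      between_participant_classify(rows, clf_config,
                                   seed = substream_seed(seed, "between-grp",
                                                         match(g, names(groups))))
    })
  }
  utils::write.csv(bind_rows(metrics, baseline, between_metrics),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)

  stats_payload <- list(
    location_tests = loc,
    anova = if (!is.null(anova_res)) tidy(anova_res),
    posthoc = posthoc,
    baseline_comparison = comparison
  )
  jsonlite::write_json(stats_payload, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")

  manifest <- list(
    package_version = as.character(utils::packageVersion("stmcit")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = as.integer(seed),
    stage_seeds = list(
      design = substream_seed(seed, "design"),
      groups = lapply(stats::setNames(names(groups), names(groups)),
                      function(g) substream_seed(seed, g))
    ),
    config_hashes = lapply(groups, rlang::hash),
    n_participants = n_participants,
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  results <- list(
    schedule = schedule, indices = indices, features = features,
    single = single, timecourses = timecourses, location_tests = loc,
    anova = anova_res, posthoc = posthoc, metrics = metrics,
    baseline = baseline, between = between_metrics,
    comparison = comparison, manifest = manifest
  )
  stage("report")
  render_report(results, file.path(out_dir, "report.md"))
  invisible(results)
}

fmt_table <- function(df, digits = 2) {
  if (is.null(df) || nrow(df) == 0) return("*(absent)*")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a markdown report of pipeline outputs
#'
#' Writes a self-contained markdown report: gaze time-course and
#' preference-index figures (PNG, next to the report), the location
#' tests, ANOVA and post hoc tables, and the classification metric
#' tables with their random-tag baseline. Numeric tables are rounded to
#' two decimals; absent stages are listed as absent.
#'
#' @param results The list returned by [run_pipeline()].
#' @param path Output path for the markdown file.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(dirname(path), "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  figs <- character(0)
  if (!is.null(results$timecourses) && nrow(results$timecourses) > 0) {
    f <- file.path(fig_dir, "timecourse.png")
    ggplot2::ggsave(f, plot_timecourse(results$timecourses),
                    width = 6, height = 4, dpi = 120)
    figs <- c(figs, "![Gaze time course](figures/timecourse.png)")
  }
  if (!is.null(results$indices) && nrow(results$indices) > 0) {
    f <- file.path(fig_dir, "preference_index.png")
    ggplot2::ggsave(f, plot_preference_index(results$indices),
                    width = 6, height = 4, dpi = 120)
    figs <- c(figs, "![Preference indices](figures/preference_index.png)")
  }
  mean_or_null <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df |>
      group_by(.data$analysis) |>
      summarise(across(c("roc_auc", "balanced_accuracy", "f1"),
                       list(mean = mean, sd = sd)), .groups = "drop")
  }
  lines <- c(
    "# STM-CIT synthetic pipeline report", "",
    paste0("Master seed: ",
           results$manifest$master_seed %||% "(none)"), "",
    figs, "",
    "## Preference indices: one-sample location tests", "",
    fmt_table(results$location_tests), "",
    "## Mixed ANOVA (Group x Phase)", "",
    fmt_table(if (!is.null(results$anova)) tidy(results$anova)), "",
    "## Tukey post hoc comparisons", "",
    fmt_table(results$posthoc), "",
    "## Classification performance (per-participant means)", "",
    fmt_table(mean_or_null(bind_rows(results$metrics, results$baseline,
                                     results$between))), "",
    "## Comparison to random-tag baseline", "",
    fmt_table(results$comparison), ""
  )
  writeLines(lines, path)
  invisible(path)
}
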