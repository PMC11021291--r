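# Per-trial fixation table on face AOIs, with face identities and
# effective-familiarity labels attached.
aoi_fixations <- function(events, schedule, labels) {
  fx <- filter(events, .data$display == "parallel",
               .data$event == "fixation", !.data$excluded)
  long <- schedule_long(schedule)
  fx <- left_join(fx, select(long, "trial_index", location = "location",
                             "face_id"),
                  by = c("trial_index", "aoi" = "location"))
  fx <- left_join(fx, select(labels$labels, "face_id", "familiar"),
                  by = "face_id")
  left_join(fx, select(labels$trials, "trial_index", "n_familiar",
                       "include"),
            by = "trial_index")
}

qualifying_trials <- function(labels) {
  filter(labels$trials, .data$include, .data$n_familiar == 1)$trial_index
}

#' Gaze time course over the parallel display
#'
#' Divides the 5,000-ms parallel display into 50 bins of 100 ms and
#' computes, for trials whose display contains exactly one effectively
#' familiar face (and that are not excluded), the proportion of each bin
#' spent on the familiar face and on the three unknown faces (their
#' mean), plus the proportion spent on the background (including
#' saccades) and in blinks. Per-trial proportions are averaged over
#' qualifying trials.
#'
#' @param events Events table from [detect_events()].
#' @param schedule The trial schedule.
#' @param labels A [apply_misidentification()] result.
#' @return A tibble with 50 rows: `bin`, `t_start`, `t_end`, `famous`,
#'   `unknown`, `background`, `blink`, `n_trials`.
#' @export
timecourse <- function(events, schedule, labels) {
  qual <- qualifying_trials(labels)
  bins <- tibble(bin = 1:50, t_start = seq(0, 4900, 100),
                 t_end = seq(100, 5000, 100))
  ev <- filter(events, .data$display == "parallel",
               .data$trial_index %in% qual)
  fx <- aoi_fixations(ev, schedule, labels)
  # classify every event's time into famous / unknown / blink / background
  tracks <- bind_rows(
    mutate(select(fx, "trial_index", "onset", "offset"),
           track = if_else(fx$familiar, "famous", "unknown")),
    mutate(select(filter(ev, .data$event == "blink"),
                  "trial_index", "onset", "offset"), track = "blink"),
    mutate(select(filter(ev, .data$event == "saccade" |
                           (.data$event == "fixation" & .data$excluded)),
                  "trial_index", "onset", "offset"), track = "background")
  )
  contrib <- tidyr::crossing(tracks, bins) |>
    mutate(ov = interval_overlap(.data$onset, .data$offset,
                                 .data$t_start, .data$t_end)) |>
    filter(.data$ov > 0) |>
    group_by(.data$trial_index, .data$bin, .data$track) |>
    summarise(prop = sum(.data$ov) / 100, .groups = "drop")
  # blink time is invisible to fixation tracks; subtract nothing: tracks
  # already partition each trial, unknown is the mean over the 3 faces
  per_trial <- contrib |>
    tidyr::pivot_wider(names_from = "track", values_from = "prop",
                       values_fill = 0)
  for (col in c("famous", "unknown", "background", "blink")) {
    if (!col %in% names(per_trial)) per_trial[[col]] <- 0
  }
  per_trial <- mutate(per_trial, unknown = .data$unknown / 3)
  out <- per_trial |>
    tidyr::complete(trial_index = qual, bin = 1:50,
                    fill = list(famous = 0, unknown = 0, background = 0,
                                blink = 0)) |>
    group_by(.data$bin) |>
    summarise(
      famous = mean(.data$famous),
      unknown = mean(.data$unknown),
      background = mean(.data$background),
      blink = mean(.data$blink),
      n_trials = dplyr::n_distinct(.data$trial_index)
    )
  left_join(bins, out, by = "bin")
}

#' Phase-wise dwell and fixation-count metrics per trial
#'
#' For each qualifying trial (exactly one effectively familiar face, not
#' excluded) and each phase (1: 200-1,000 ms; 2: 1,001-5,000 ms),
#' computes dwell time on the familiar face and the pooled mean over the
#' three unknown faces (divided by three), and the corresponding fixation
#' counts. Dwell is the overlap of fixations with the phase window; a
#' fixation's count is credited to the phase containing its onset, and
#' gaze before 200 ms contributes to neither phase.
#'
#' @inheritParams timecourse
#' @return A tibble with one row per qualifying trial and phase:
#'   `trial_index`, `phase`, `dwell_famous`, `dwell_unknown_mean`,
#'   `fix_count_famous`, `fix_count_unknown_mean`.
#' @export
phase_metrics <- function(events, schedule, labels) {
  qual <- qualifying_trials(labels)
  fx <- aoi_fixations(events, schedule, labels) |>
    filter(.data$trial_index %in% qual)
  per_phase <- purrr::map_dfr(c(1, 2), function(ph) {
    win <- PHASE_WINDOWS[[as.character(ph)]]
    fx |>
      mutate(
        ov = interval_overlap(.data$onset, .data$offset, win[1], win[2]),
        counted = .data$onset >= win[1] & .data$onset < win[2]
      ) |>
      group_by(.data$trial_index) |>
      summarise(
        phase = ph,
        dwell_famous = sum(.data$ov[.data$familiar]),
        dwell_unknown_mean = sum(.data$ov[!.data$familiar]) / 3,
        fix_count_famous = sum(.data$counted[.data$familiar]),
        fix_count_unknown_mean = sum(.data$counted[!.data$familiar]) / 3,
        .groups = "drop"
      )
  })
  per_phase |>
    tidyr::complete(trial_index = qual, phase = c(1, 2),
                    fill = list(dwell_famous = 0, dwell_unknown_mean = 0,
                                fix_count_famous = 0,
                                fix_count_unknown_mean = 0)) |>
    arrange(.data$trial_index, .data$phase)
}

#' Preference index per phase
#'
#' The preference index is the mean over qualifying trials of the signed
#' difference between the proportion of phase time spent on the familiar
#' face and on the unknown faces (pooled over three and divided by
#' three); positive values indicate longer fixation of the familiar
#' face. The proportion denominator is the phase duration (800 ms for
#' phase 1, 4,000 ms for phase 2). The fixation-count difference
#' (`delta_fix`) is returned alongside.
#'
#' @param metrics Output of [phase_metrics()].
#' @param participant_id Optional identifier column value.
#' @return A tibble with one row per phase: `participant_id` (if given),
#'   `phase`, `index`, `delta_fix`, `n_trials`.
#' @export
preference_index <- function(metrics, participant_id = NULL) {
  if (nrow(metrics) == 0) {
    abort("No qualifying trials: preference index undefined.",
          class = "stmcit_insufficient_data")
  }
  out <- metrics |>
    group_by(.data$phase) |>
    summarise(
      index = mean((.data$dwell_famous - .data$dwell_unknown_mean) /
                     PHASE_DURATION[as.character(.data$phase)]),
      delta_fix = mean(.data$fix_count_famous -
                         .data$fix_count_unknown_mean),
      n_trials = n(),
      .groups = "drop"
    )
  if (!is.null(participant_id)) {
    out <- mutate(out, participant_id = participant_id, .before = 1)
  }
  out
}

#' Count visits per face AOI
#'
#' A visit is a maximal run of consecutive fixations on one picture
#' before a saccade carries gaze outside it; fixations on the background
#' (or on another picture) break the run.
#'
#' @param fixations Fixation events of one trial in temporal order, with
#'   an `aoi` column.
#' @return A tibble `aoi`, `visits` covering the four grid locations.
#' @export
#' @examples
#' fx <- tibble::tibble(aoi = c("top_left", "background", "top_left"))
#' count_visits(fx)  # two visits to top_left
count_visits <- function(fixations) {
  base <- tibble(aoi = GRID_LOCATIONS, visits = 0L)
  if (nrow(fixations) == 0) return(base)
  runs <- rle(fixations$aoi)$values
  counts <- table(factor(runs[runs %in% GRID_LOCATIONS],
                         levels = GRID_LOCATIONS))
  tibble(aoi = GRID_LOCATIONS, visits = as.integer(counts))
}

#' Per-face classification feature vectors
#'
#' Aggregates, for each of the 64 faces, the four classification
#' predictors over the face's qualifying parallel-display appearances:
#' dwell time in phase 1 and phase 2, total fixation count over the full
#' display, and total visit count. Effectively familiar faces aggregate
#' over their (non-excluded) appearances; non-familiar faces aggregate
#' only over appearances in trials containing no effectively familiar
#' face — the simulated "unknowledgeable" observations. Aggregation is
#' the mean per appearance. A face without qualifying appearances falls
#' back to all its non-excluded appearances with a warning.
#'
#' @inheritParams timecourse
#' @return A tibble with 64 rows: `face_id`, `label` (effectively
#'   familiar), `dwell_phase1`, `dwell_phase2`, `fixation_count`,
#'   `visit_count`, `n_appearances`.
#' @export
aggregate_face_features <- function(events, schedule, labels) {
  long <- schedule_long(schedule)
  fx_all <- filter(events, .data$display == "parallel",
                   .data$event == "fixation")
  # per trial x location: dwell per phase, total fixations, visits
  per_loc <- purrr::map_dfr(split(fx_all, fx_all$trial_index), function(fx) {
    visits <- count_visits(fx)
    stats <- fx |>
      filter(.data$aoi %in% GRID_LOCATIONS) |>
      group_by(aoi = .data$aoi) |>
      summarise(
        dwell_phase1 = sum(interval_overlap(.data$onset, .data$offset,
                                            PHASE_WINDOWS[["1"]][1],
                                            PHASE_WINDOWS[["1"]][2])),
        dwell_phase2 = sum(interval_overlap(.data$onset, .data$offset,
                                            PHASE_WINDOWS[["2"]][1],
                                            PHASE_WINDOWS[["2"]][2])),
        fixation_count = n(),
        .groups = "drop"
      )
    out <- left_join(visits, stats, by = "aoi")
    out$trial_index <- fx$trial_index[1]
    out
  })
  per_loc <- per_loc |>
    tidyr::complete(trial_index = schedule$trial_index, aoi = GRID_LOCATIONS,
                    fill = list(visits = 0L)) |>
    mutate(across(c("dwell_phase1", "dwell_phase2", "fixation_count"),
                  \(v) tidyr::replace_na(v, 0)))
  app <- left_join(per_loc, select(long, "trial_index", "location",
                                   "face_id"),
                   by = c("trial_index", "aoi" = "location")) |>
    left_join(select(labels$labels, "face_id", "familiar"), by = "face_id") |>
    left_join(select(labels$trials, "trial_index", "n_familiar", "include"),
              by = "trial_index")

  agg_rows <- app |>
    filter(.data$include,
           .data$familiar | .data$n_familiar == 0)
  fallback_ids <- setdiff(labels$labels$face_id, unique(agg_rows$face_id))
  if (length(fallback_ids) > 0) {
    warn(paste0(
      "No qualifying appearances for ",
      paste(fallback_ids, collapse = ", "),
      "; falling back to all non-excluded appearances."
    ))
    agg_rows <- bind_rows(
      agg_rows,
      filter(app, .data$face_id %in% fallback_ids, .data$include)
    )
  }
  out <- agg_rows |>
    group_by(.data$face_id, label = .data$familiar) |>
    summarise(
      dwell_phase1 = mean(.data$dwell_phase1),
      dwell_phase2 = mean(.data$dwell_phase2),
      fixation_count = mean(.data$fixation_count),
      visit_count = mean(.data$visits),
      n_appearances = n(),
      .groups = "drop"
    )
  arrange(left_join(select(labels$labels, "face_id"), out, by = "face_id"),
          match(.data$face_id, labels$labels$face_id))
}

#' Ocular and manual measures for the single-face display
#'
#' Per face type (effectively familiar vs unknown): the mean duration of
#' detected fixations during the single-face display, the mean reaction
#' time and the proportion of correct responses. Trials without a
#' response inside the 5,000-ms window are excluded from all three
#' measures.
#'
#' @param events Events table from [detect_events()].
#' @param schedule The trial schedule.
#' @param responses The recording's response table.
#' @param labels A [apply_misidentification()] result.
#' @return A tibble with rows `famous` and `unknown`: `face_type`,
#'   `mean_fixation_duration`, `mean_rt`, `prop_correct`, `n_trials`.
#' @export
single_face_measures <- function(events, schedule, responses, labels) {
  resp <- left_join(
    responses,
    select(schedule, "trial_index", "single_face"),
    by = "trial_index"
  ) |>
    left_join(select(labels$labels, "face_id", "familiar"),
              by = c("single_face" = "face_id")) |>
    filter(!.data$no_response)
  if (nrow(resp) == 0) {
    abort("All trials lack a response: single-face measures undefined.",
          class = "stmcit_insufficient_data")
  }
  fx <- filter(events, .data$display == "single", .data$event == "fixation",
               .data$aoi == "single") |>
    dplyr::semi_join(resp, by = "trial_index") |>
    left_join(select(resp, "trial_index", "familiar"), by = "trial_index")
  fix_means <- fx |>
    group_by(.data$familiar) |>
    summarise(mean_fixation_duration = mean(.data$duration),
              .groups = "drop")
  resp |>
    group_by(.data$familiar) |>
    summarise(
      mean_rt = mean(.data$rt_ms),
      prop_correct = mean(.data$correct),
      n_trials = n(),
      .groups = "drop"
    ) |>
    left_join(fix_means, by = "familiar") |>
    mutate(face_type = if_else(.data$familiar, "famous", "unknown"),
           .before = 1) |>
    select("face_type", "mean_fixation_duration", "mean_rt",
           "prop_correct", "n_trials")
}
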