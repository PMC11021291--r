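#' Analyze one simulated or recorded participant
#'
#' Convenience wrapper chaining event detection, misidentification
#' relabeling, phase metrics, preference indices, per-face feature
#' aggregation and single-face measures for one recording.
#'
#' @param recording A `cit_recording`.
#' @param schedule The schedule the recording was collected under.
#' @param geometry A [screen_geometry()].
#' @param strict Strict misidentification exclusion mode, see
#'   [apply_misidentification()].
#' @param include_timecourse Also compute the 50-bin [timecourse()].
#' @return A list of class `cit_participant_analysis` with elements
#'   `participant_id`, `events`, `labels`, `metrics`, `indices`,
#'   `features`, `single`, and optionally `timecourse`.
#' @export
#' @examples
#' sched <- generate_schedule(cit_faces(), seed = 1)
#' rec <- simulate_participant(sched, gaze_config(), seed = 1)
#' ana <- analyze_participant(rec, sched)
#' ana$indices
analyze_participant <- function(recording, schedule,
                                geometry = screen_geometry(),
                                strict = FALSE,
                                include_timecourse = FALSE) {
  events <- detect_events(recording, geometry)
  labels <- apply_misidentification(schedule, recording$posttest,
                                    strict = strict)
  metrics <- phase_metrics(events, schedule, labels)
  indices <- preference_index(metrics,
                              participant_id = recording$participant_id)
  features <- aggregate_face_features(events, schedule, labels)
  single <- single_face_measures(events, schedule, recording$responses,
                                 labels)
  out <- list(
    participant_id = recording$participant_id,
    events = events,
    labels = labels,
    metrics = metrics,
    indices = indices,
    features = features,
    single = single
  )
  if (include_timecourse) {
    out$timecourse <- timecourse(events, schedule, labels)
  }
  structure(out, class = "cit_participant_analysis")
}

#' Analyze a cohort of recordings
#'
#' @param recordings List of `cit_recording` (e.g. [simulate_cohort()]).
#' @inheritParams analyze_participant
#' @return A list of class `cit_cohort_analysis`: `participants` (the
#'   per-participant analyses), `indices` (stacked preference indices),
#'   `features` (stacked per-face feature tables with `participant_id`),
#'   `single` (stacked single-face measures).
#' @export
analyze_cohort <- function(recordings, schedule,
                           geometry = screen_geometry(), strict = FALSE,
                           include_timecourse = FALSE) {
  analyses <- lapply(recordings, analyze_participant, schedule = schedule,
                     geometry = geometry, strict = strict,
                     include_timecourse = include_timecourse)
  structure(
    list(
      participants = analyses,
      indices = purrr::map_dfr(analyses, "indices"),
      features = purrr::map_dfr(analyses, function(a) {
        mutate(a$features, participant_id = a$participant_id, .before = 1)
      }),
      single = purrr::map_dfr(analyses, function(a) {
        mutate(a$single, participant_id = a$participant_id, .before = 1)
      })
    ),
    class = "cit_cohort_analysis"
  )
}
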