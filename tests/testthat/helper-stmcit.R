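# Shared fixtures. Expensive objects are built lazily and memoised for
# the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

test_schedule <- function(seed = 1) {
  memo(paste0("schedule", seed), generate_schedule(cit_faces(), seed = seed))
}

# Deterministic, noiseless, blink-free participant: the generator's own
# event log is an exact oracle for the detector.
clean_config <- function(...) {
  gaze_config(theta_orient = 0, theta_avoid = 0, blink_rate = 0,
              noise_sd = 0, tremor_sd = 0, ...)
}

clean_recording <- function() {
  memo("clean_rec",
       simulate_participant(test_schedule(), clean_config(), seed = 11))
}

noisy_recording <- function() {
  memo("noisy_rec",
       simulate_participant(test_schedule(), gaze_config(blink_rate = 0.5),
                            seed = 12))
}

perfect_posttest <- function() {
  faces <- cit_faces()
  tibble::tibble(face_id = faces$face_id, judged_famous = faces$famous)
}

perfect_labels <- function(schedule = test_schedule()) {
  apply_misidentification(schedule, perfect_posttest())
}

# Hand-built label object: only the given trials qualify (include and
# exactly one familiar face), so feature functions can be exercised on
# hand-crafted event tables.
labels_for_trials <- function(trial_idx, schedule = test_schedule()) {
  lab <- perfect_labels(schedule)
  lab$trials$include <- lab$trials$trial_index %in% trial_idx
  lab
}

# Synthetic 64-row feature table with a controllable class separation
# (in units of the unknown-class SD).
synthetic_features <- function(separation, seed = 1,
                               participant_id = "S01") {
  withr::with_seed(seed, {
    label <- rep(c(TRUE, FALSE), c(8, 56))
    tibble::tibble(
      participant_id = participant_id,
      face_id = sprintf("img%02d", 1:64),
      label = label,
      dwell_phase1 = rnorm(64, 200 + separation * 50 * label, 50),
      dwell_phase2 = rnorm(64, 800 - separation * 150 * label, 150),
      fixation_count = rnorm(64, 10 - separation * label, 1),
      visit_count = rnorm(64, 6 - separation * label, 1)
    )
  })
}

# The 15-participant study-scale cohort used by the acceptance checks:
# theta set to the reported group-mean preference indices.
acceptance_cohort <- function() {
  memo("acceptance_cohort", {
    sched <- test_schedule(1)
    recs <- lapply(1:15, function(i) {
      simulate_participant(
        sched, gaze_config(),
        seed = substream_seed(1, "participant", i),
        participant_id = sprintf("P%02d", i)
      )
    })
    suppressWarnings(analyze_cohort(recs, sched))
  })
}

expect_all_pass <- function(report) {
  expect_true(all(report$pass),
              info = paste("failing checks:",
                           paste(report$check[!report$pass], collapse = ", ")))
}
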