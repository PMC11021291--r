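# Build a minimal parallel-display events table for hand-computed cases.
events_row <- function(trial, onset, offset, aoi,
                       event = "fixation") {
  tibble::tibble(
    trial_index = trial, display = "parallel", event = event,
    onset = onset, offset = offset, duration = offset - onset,
    cx = NA_real_, cy = NA_real_, aoi = aoi,
    excluded = !is.na(aoi) & aoi == "background"
  )
}

famous_location <- function(trial, schedule = test_schedule()) {
  long <- schedule_long(schedule)
  long$location[long$trial_index == trial &
                  grepl("^fam", long$face_id)][1]
}

test_that("relabeling: a perfect post-test changes nothing", {
  lab <- perfect_labels()
  expect_equal(lab$labels$familiar, lab$labels$famous)
  expect_true(all(lab$trials$include))
  expect_equal(unique(lab$trials$reason), "none")
  expect_error(
    apply_misidentification(test_schedule(), perfect_posttest()[-1, ]),
    class = "stmcit_data_error"
  )
})

test_that("relabeling: exclusion rules fire on the exact quoted conditions", {
  sched <- test_schedule()
  long <- schedule_long(sched)
  fame <- stats::setNames(cit_faces()$famous, cit_faces()$face_id)
  # a false recognition co-occurring with a celebrity
  fam_trial <- long$trial_index[fame[long$face_id]][1]
  companion <- long$face_id[long$trial_index == fam_trial &
                              !fame[long$face_id]][1]
  pt <- perfect_posttest()
  pt$judged_famous[pt$face_id == companion] <- TRUE
  lab <- apply_misidentification(sched, pt)
  tr <- lab$trials[lab$trials$trial_index == fam_trial, ]
  expect_false(tr$include)
  expect_match(tr$reason, "celebrity")
  expect_true(lab$labels$familiar[lab$labels$face_id == companion])

  # two false recognitions in one no-famous display
  nofam_trial <- setdiff(long$trial_index,
                         long$trial_index[fame[long$face_id]])[1]
  pair <- long$face_id[long$trial_index == nofam_trial][1:2]
  pt2 <- perfect_posttest()
  pt2$judged_famous[pt2$face_id %in% pair] <- TRUE
  lab2 <- apply_misidentification(sched, pt2)
  tr2 <- lab2$trials[lab2$trials$trial_index == nofam_trial, ]
  expect_false(tr2$include)
  expect_match(tr2$reason, ">1 false recognition")

  # strict mode removes every trial containing the misidentified face
  lab3 <- apply_misidentification(sched, pt, strict = TRUE)
  affected <- long$trial_index[long$face_id == companion]
  expect_true(all(!lab3$trials$include[lab3$trials$trial_index %in%
                                         affected]))
})

test_that("timecourse bin overlap arithmetic and qualifying-trial averaging", {
  sched <- test_schedule()
  lab <- perfect_labels(sched)
  trial <- qual <- stmcit:::qualifying_trials(lab)[1]
  lab <- labels_for_trials(trial, sched)
  floc <- famous_location(trial, sched)
  other <- setdiff(c("top_left", "top_right", "bottom_left",
                     "bottom_right"), floc)
  ev <- dplyr::bind_rows(
    events_row(trial, 150, 250, floc),
    events_row(trial, 250, 5000, other[1])
  )
  tc <- timecourse(ev, sched, lab)
  expect_equal(nrow(tc), 50)
  expect_equal(tc$famous[tc$bin == 1], 0)
  expect_equal(tc$famous[tc$bin == 2], 0.5)  # 150-200 ms: 50 of 100 ms
  expect_equal(tc$famous[tc$bin == 3], 0.5)  # 200-250 ms
  expect_equal(tc$famous[tc$bin == 4], 0)
  expect_equal(tc$unknown[tc$bin == 30], 1 / 3)
  # a full-trial fixation on the famous face fills every bin
  ev2 <- events_row(trial, 0, 5000, floc)
  tc2 <- timecourse(ev2, sched, lab)
  expect_true(all(tc2$famous == 1))
  expect_true(all(tc2$unknown == 0))
})

test_that("bin conservation holds in every bin of a full recording", {
  ana <- acceptance_cohort()
  a <- ana$participants[[1]]
  tc <- timecourse(a$events, test_schedule(), a$labels)
  total <- tc$famous + 3 * tc$unknown + tc$background + tc$blink
  expect_equal(total, rep(1, 50), tolerance = 1e-8)
})

test_that("phase metrics: window clipping, onset crediting, pooling by three", {
  sched <- test_schedule()
  lab0 <- perfect_labels(sched)
  trial <- stmcit:::qualifying_trials(lab0)[1]
  lab <- labels_for_trials(trial, sched)
  floc <- famous_location(trial, sched)
  ev <- events_row(trial, 0, 5000, floc)
  pm <- phase_metrics(ev, sched, lab)
  expect_equal(pm$dwell_famous[pm$phase == 1], 800)
  expect_equal(pm$dwell_famous[pm$phase == 2], 4000)
  # onset before 200 ms: the fixation is counted in neither phase
  expect_equal(pm$fix_count_famous, c(0, 0))
  expect_equal(pm$dwell_unknown_mean, c(0, 0))
  expect_equal(pm$fix_count_unknown_mean, c(0, 0))
  # a fixation spanning the phase boundary splits its dwell by overlap
  # and credits its count to the onset phase
  ev2 <- events_row(trial, 600, 1400, floc)
  pm2 <- phase_metrics(ev2, sched, lab)
  expect_equal(pm2$dwell_famous, c(400, 400))
  expect_equal(pm2$fix_count_famous, c(1, 0))
})

test_that("preference index arithmetic and insufficient-data handling", {
  sched <- test_schedule()
  lab0 <- perfect_labels(sched)
  trials <- stmcit:::qualifying_trials(lab0)[1:4]
  lab <- labels_for_trials(trials, sched)
  ev <- dplyr::bind_rows(lapply(trials, function(tr) {
    floc <- famous_location(tr, sched)
    other <- setdiff(c("top_left", "top_right", "bottom_left",
                       "bottom_right"), floc)
    dplyr::bind_rows(
      events_row(tr, 200, 500, floc),              # famous: 300 ms phase 1
      events_row(tr, 500, 680, other[1]),          # unknown a: 180 ms
      events_row(tr, 680, 860, other[2]),          # unknown b: 180 ms
      events_row(tr, 860, 1000, other[3])          # unknown c: 140 ms...
    )
  }))
  # pooled unknown dwell = (180+180+140)/3 = 500/3 ms
  pm <- phase_metrics(ev, sched, lab)
  pref <- preference_index(pm)
  expected <- (300 - 500 / 3) / 800
  expect_equal(pref$index[pref$phase == 1], expected)
  expect_error(preference_index(pm[0, ]),
               class = "stmcit_insufficient_data")
})

test_that("per-participant indices are bounded and near zero for an unbiased chain", {
  ana <- acceptance_cohort()
  expect_true(all(abs(ana$indices$index) <= 1))
})

test_that("visit counting: runs, background breaks, empty input", {
  fx <- tibble::tibble(aoi = c("top_left", "top_left", "top_right",
                               "top_left"))
  v <- count_visits(fx)
  expect_equal(v$visits[v$aoi == "top_left"], 2L)
  expect_equal(v$visits[v$aoi == "top_right"], 1L)
  expect_equal(sum(count_visits(fx[0, ])$visits), 0L)
  fx2 <- tibble::tibble(aoi = c("top_left", "background", "top_left"))
  expect_equal(count_visits(fx2)$visits[1], 2L)
})

test_that("face feature aggregation means over qualifying appearances", {
  sched <- test_schedule()
  long <- schedule_long(sched)
  fam_id <- "fam_m1"
  fam_trials <- long$trial_index[long$face_id == fam_id]
  expect_length(fam_trials, 4)
  lab <- labels_for_trials(fam_trials, sched)
  dwells <- c(500, 700, 600, 600)
  ev <- dplyr::bind_rows(lapply(seq_along(fam_trials), function(k) {
    tr <- fam_trials[k]
    loc <- long$location[long$trial_index == tr & long$face_id == fam_id]
    events_row(tr, 1000, 1000 + dwells[k], loc)
  }))
  suppressWarnings(feat <- aggregate_face_features(ev, sched, lab))
  row <- feat[feat$face_id == fam_id, ]
  expect_equal(row$dwell_phase2, 600)
  expect_equal(row$n_appearances, 4L)
  expect_equal(row$fixation_count, 1)
  expect_equal(row$visit_count, 1)
})

test_that("feature tables cover all 64 faces with sane invariants", {
  ana <- acceptance_cohort()
  feat <- ana$participants[[2]]$features
  expect_equal(nrow(feat), 64)
  expect_equal(sum(is.na(feat$dwell_phase2)), 0)
  expect_true(all(feat$visit_count <= feat$fixation_count + 1e-9))
  # avoidance: familiar faces dwell less in phase 2 than unknown ones
  ana_means <- dplyr::summarise(
    dplyr::group_by(ana$features, label),
    d2 = mean(dwell_phase2)
  )
  expect_lt(ana_means$d2[ana_means$label], ana_means$d2[!ana_means$label])
})

test_that("phase dwell additivity: phases plus the first 200 ms equal total dwell", {
  ana <- acceptance_cohort()
  a <- ana$participants[[3]]
  lab <- a$labels
  qual <- stmcit:::qualifying_trials(lab)
  fx <- dplyr::filter(a$events, display == "parallel", event == "fixation",
                      !excluded, trial_index %in% qual)
  long <- schedule_long(test_schedule())
  fx <- dplyr::left_join(fx, long, by = c("trial_index", "aoi" = "location"))
  fx <- dplyr::left_join(fx, lab$labels[, c("face_id", "familiar")],
                         by = "face_id")
  early <- dplyr::summarise(
    dplyr::group_by(fx, trial_index),
    tot = sum(pmin(offset, 5000) - onset),
    early = sum(pmax(0, pmin(offset, 200) - pmin(onset, 200)))
  )
  pm <- a$metrics |>
    dplyr::group_by(trial_index) |>
    dplyr::summarise(ph = sum(dwell_famous + 3 * dwell_unknown_mean))
  j <- dplyr::inner_join(early, pm, by = "trial_index")
  expect_equal(j$ph + j$early, j$tot, tolerance = 1e-8)
})

test_that("single-face measures: arithmetic and no-response exclusion", {
  sched <- test_schedule()
  lab <- perfect_labels(sched)
  fame <- stats::setNames(cit_faces()$famous, cit_faces()$face_id)
  fam_tr <- sched$trial_index[fame[sched$single_face]][1:2]
  unk_tr <- sched$trial_index[!fame[sched$single_face]][1]
  other <- sched$trial_index[!fame[sched$single_face]][2]
  responses <- tibble::tibble(
    trial_index = c(fam_tr, unk_tr, other),
    response = c("yes", "yes", "no", NA),
    correct = c(TRUE, TRUE, TRUE, NA),
    rt_ms = c(1000, 1010, 1290, NA),
    no_response = c(FALSE, FALSE, FALSE, TRUE)
  )
  ev <- tibble::tibble(
    trial_index = rep(c(fam_tr, unk_tr, other), each = 1),
    display = "single", event = "fixation",
    onset = 0, offset = c(240, 260, 250, 400),
    duration = c(240, 260, 250, 400),
    cx = 0, cy = 0, aoi = "single", excluded = FALSE
  )
  sm <- single_face_measures(ev, sched, responses, lab)
  expect_equal(sm$mean_rt[sm$face_type == "famous"], 1005)
  expect_equal(sm$mean_rt[sm$face_type == "unknown"], 1290)
  expect_equal(sm$prop_correct, c(1, 1), ignore_attr = TRUE)
  expect_equal(sm$mean_fixation_duration[sm$face_type == "famous"], 250)
  expect_equal(sm$n_trials[sm$face_type == "unknown"], 1L)
  all_nr <- dplyr::mutate(responses, no_response = TRUE)
  expect_error(single_face_measures(ev, sched, all_nr, lab),
               class = "stmcit_insufficient_data")
})
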