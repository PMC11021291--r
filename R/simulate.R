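# Sample-level rendering of one trial: piecewise-linear gaze trace through
# the fixation positions (constant during fixations, linear during
# saccades), per-sample tremor during fixations, optional blink gaps.
render_trace <- function(fix, t_end, config, sample_rate = 1000) {
  dt <- 1000 / sample_rate
  times <- seq(0, t_end - dt, by = dt)
  knot_t <- as.vector(rbind(fix$onset, fix$offset))
  knot_x <- as.vector(rbind(fix$x, fix$x))
  knot_y <- as.vector(rbind(fix$y, fix$y))
  x <- approx(knot_t, knot_x, xout = times, rule = 2, ties = "ordered")$y
  y <- approx(knot_t, knot_y, xout = times, rule = 2, ties = "ordered")$y
  if (config$tremor_sd > 0) {
    idx <- findInterval(times, fix$onset)
    in_fix <- idx > 0 & times < fix$offset[pmax(idx, 1)]
    x[in_fix] <- x[in_fix] + rnorm(sum(in_fix), 0, config$tremor_sd)
    y[in_fix] <- y[in_fix] + rnorm(sum(in_fix), 0, config$tremor_sd)
  }
  tibble(time_ms = times, x_deg = x, y_deg = y, valid = TRUE)
}

#' Simulate one participant's STM-CIT session
#'
#' Generates per-trial 1,000-Hz gaze traces for the 5,000-ms four-face
#' parallel display and the single-face display, key responses, and
#' post-test famous/unknown judgments. The parallel-display scan path is
#' a Markov chain over the four AOIs and the background: the first
#' fixation is at screen center, fixation durations are lognormal,
#' saccades follow the main-sequence duration rule, and transition
#' weights are multiplicatively biased toward faces the participant finds
#' familiar before 1,000 ms (`theta_orient`) and away from them
#' afterwards (`theta_avoid`), with multipliers calibrated by
#' [calibrate_bias()] so the expected phase dwell-proportion differences
#' equal the theta values. Post-test judgments are drawn first (misses
#' and false recognitions per the configured rates) and the gaze bias
#' follows the participant's effective familiarity, so misidentified
#' faces attract or repel gaze like truly familiar ones.
#'
#' @param schedule A [generate_schedule()] result.
#' @param config A [gaze_config()].
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param participant_id Identifier stored with the data.
#' @param geometry A [screen_geometry()].
#' @return A list of class `cit_recording` with elements `samples`
#'   (tibble: `trial_index`, `display`, `time_ms`, `x_deg`, `y_deg`,
#'   `valid`), `events` (the generator's own event log: `trial_index`,
#'   `display`, `event`, `aoi`, `onset`, `offset`), `responses`
#'   (`trial_index`, `response`, `correct`, `rt_ms`, `no_response`),
#'   `posttest` (`face_id`, `judged_famous`), and the `participant_id`,
#'   `config` and `seed` used.
#' @export
#' @examples
#' sched <- generate_schedule(cit_faces(), seed = 1)
#' rec <- simulate_participant(sched, gaze_config(theta_orient = 0,
#'   theta_avoid = 0, blink_rate = 0), seed = 1)
#' head(rec$samples)
simulate_participant <- function(schedule, config = gaze_config(), seed = 1L,
                                 participant_id = "P01",
                                 geometry = screen_geometry()) {
  faces <- attr(schedule, "faces") %||% cit_faces()
  check_face_set(faces)
  # calibrate outside the seeded block: cached, internally seeded
  if (config$theta_orient != 0 || config$theta_avoid != 0) {
    m1 <- calibrate_bias(config$theta_orient, 1, config, geometry)
    m2 <- calibrate_bias(config$theta_avoid, 2, config, geometry,
                         m_phase1 = m1)
  } else {
    m1 <- m2 <- 1
  }
  withr::with_seed(substream_seed(seed, "simulate"), {
    n_trials <- nrow(schedule)
    flip_famous <- rbinom(nrow(faces), 1, config$miss_rate) == 1
    flip_unknown <- rbinom(nrow(faces), 1, config$false_recognition_rate) == 1
    posttest <- tibble(
      face_id = faces$face_id,
      judged_famous = if_else(faces$famous, !flip_famous, flip_unknown)
    )
    familiar_ids <- posttest$face_id[posttest$judged_famous]

    par_mat <- as.matrix(schedule[, GRID_LOCATIONS])
    bias_mat <- matrix(par_mat %in% familiar_ids, nrow = n_trials)
    ev <- sim_chain(bias_mat, m1, m2, config, geometry)

    boxes <- geometry$boxes
    centers_x <- c(boxes$cx[match(GRID_LOCATIONS, boxes$aoi)], 0)
    centers_y <- c(boxes$cy[match(GRID_LOCATIONS, boxes$aoi)], 0)

    samples <- vector("list", 2 * n_trials)
    events <- vector("list", 2 * n_trials)

    for (i in seq_len(n_trials)) {
      tr <- ev[ev$trial == i, ]
      fx <- tr[tr$event == "fixation", ]
      n_fix <- nrow(fx)
      off_x <- c(0, rnorm(n_fix - 1, 0, config$noise_sd))
      off_y <- c(0, rnorm(n_fix - 1, 0, config$noise_sd))
      fx$x <- centers_x[fx$state] + off_x
      fx$y <- centers_y[fx$state] + off_y
      trace <- render_trace(fx, 5000, config, geometry$sample_rate)

      blink_log <- NULL
      n_blinks <- rpois(1, config$blink_rate)
      if (n_blinks > 0) {
        starts <- fx$onset[sample.int(n_fix, min(n_blinks, n_fix))]
        durs <- runif(length(starts), config$blink_range[1],
                      config$blink_range[2])
        ends <- pmin(starts + durs, 5000)
        for (b in seq_along(starts)) {
          hit <- trace$time_ms >= starts[b] & trace$time_ms < ends[b]
          trace$valid[hit] <- FALSE
          trace$x_deg[hit] <- NA_real_
          trace$y_deg[hit] <- NA_real_
        }
        blink_log <- tibble(event = "blink", aoi = NA_character_,
                            onset = starts, offset = ends)
      }
      trial_events <- bind_rows(
        tibble(event = tr$event, aoi = CHAIN_STATES[tr$state],
               onset = tr$onset, offset = tr$offset),
        blink_log
      )
      samples[[i]] <- mutate(trace, trial_index = schedule$trial_index[i],
                             display = "parallel", .before = 1)
      events[[i]] <- mutate(trial_events, trial_index = schedule$trial_index[i],
                            display = "parallel", .before = 1)
    }

    # single-face display: one-AOI scanning until the response (or the
    # 5,000-ms deadline for no-response trials)
    single_familiar <- schedule$single_face %in% familiar_ids
    no_resp <- rbinom(n_trials, 1, config$no_response_rate) == 1
    rt_mean <- if_else(single_familiar, config$rt_mean_famous,
                       config$rt_mean_unknown)
    rt_sd <- if_else(single_familiar, config$rt_sd_famous, config$rt_sd_unknown)
    rt <- pmin(pmax(rnorm(n_trials, rt_mean, rt_sd), 300), 4999)
    rt[no_resp] <- NA_real_
    acc <- if_else(single_familiar, config$acc_famous, config$acc_unknown)
    correct <- rbinom(n_trials, 1, acc) == 1
    correct[no_resp] <- NA
    response <- if_else(correct, schedule$correct_answer,
                        if_else(schedule$correct_answer == "yes", "no", "yes"))

    half_w <- geometry$picture_width / 2 - 0.5
    half_h <- geometry$picture_height / 2 - 0.5
    for (i in seq_len(n_trials)) {
      t_end <- if (no_resp[i]) 5000 else rt[i]
      fx <- single_fixation_seq(t_end, half_w, half_h, config)
      trace <- render_trace(fx[fx$event == "fixation", ], ceiling(t_end),
                            config, geometry$sample_rate)
      samples[[n_trials + i]] <- mutate(
        trace, trial_index = schedule$trial_index[i],
        display = "single", .before = 1
      )
      events[[n_trials + i]] <- mutate(
        tibble(event = fx$event, aoi = "single",
               onset = fx$onset, offset = fx$offset),
        trial_index = schedule$trial_index[i], display = "single", .before = 1
      )
    }

    structure(
      list(
        participant_id = participant_id,
        samples = arrange(bind_rows(samples), .data$trial_index,
                          .data$display, .data$time_ms),
        events = arrange(bind_rows(events), .data$trial_index, .data$display,
                         .data$onset),
        responses = tibble(
          trial_index = schedule$trial_index,
          response = if_else(no_resp, NA_character_, response),
          correct = correct,
          rt_ms = rt,
          no_response = no_resp
        ),
        posttest = posttest,
        config = config,
        seed = as.integer(seed)
      ),
      class = "cit_recording"
    )
  })
}

# Fixation sequence within the single-face box: lognormal durations,
# refixations at least 1.2 degrees apart so every repositioning saccade is
# kinematically detectable.
single_fixation_seq <- function(t_end, half_w, half_h, config) {
  mu <- log(config$fixation_median)
  sg <- config$fixation_sigma
  pos <- c(0, 0)
  t <- 0
  rows <- list()
  k <- 0
  while (t < t_end) {
    dur <- rlnorm(1, mu, sg)
    off <- min(t + dur, t_end)
    k <- k + 1
    rows[[k]] <- tibble(event = "fixation", onset = t, offset = off,
                        x = pos[1], y = pos[2])
    if (off >= t_end) break
    repeat {
      new_pos <- c(
        max(min(rnorm(1, 0, 1.5), half_w), -half_w),
        max(min(rnorm(1, 0, 1.5), half_h), -half_h)
      )
      if (sqrt(sum((new_pos - pos)^2)) >= 1.2) break
    }
    amp <- sqrt(sum((new_pos - pos)^2))
    sdur <- config$saccade_intercept + config$saccade_slope * amp
    if (off + sdur + 20 >= t_end) {
      # hold the fixation to the display offset rather than end mid-saccade
      rows[[k]]$offset <- t_end
      break
    }
    k <- k + 1
    rows[[k]] <- tibble(event = "saccade", onset = off, offset = off + sdur,
                        x = NA_real_, y = NA_real_)
    t <- off + sdur
    pos <- new_pos
  }
  bind_rows(rows)
}

#' Simulate a cohort of participants
#'
#' @param schedule A [generate_schedule()] result shared by the cohort.
#' @param config A [gaze_config()].
#' @param n_participants Cohort size.
#' @param seed Master seed; participant `i` uses substream
#'   `substream_seed(seed, "participant", i)`.
#' @param geometry A [screen_geometry()].
#' @return A list of `cit_recording`, named by participant id.
#' @export
simulate_cohort <- function(schedule, config = gaze_config(),
                            n_participants = 15, seed = 1L,
                            geometry = screen_geometry()) {
  ids <- sprintf("P%02d", seq_len(n_participants))
  recs <- lapply(seq_len(n_participants), function(i) {
    simulate_participant(
      schedule, config,
      seed = substream_seed(seed, "participant", i),
      participant_id = ids[i], geometry = geometry
    )
  })
  stats::setNames(recs, ids)
}
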