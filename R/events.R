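#' Gaze kinematics from raw samples
#'
#' Speed is computed per axis with a 5-point central difference and
#' combined as the Euclidean magnitude; acceleration magnitude is the
#' central difference of speed. The first/last two samples use one-sided
#' (forward/backward and 3-point central) differences. `NA` positions
#' (blinks) propagate to `NA` kinematics.
#'
#' @param samples Tibble with `time_ms`, `x_deg`, `y_deg` for one
#'   uninterrupted stream (one trial and display).
#' @param sample_rate Sampling rate in Hz.
#' @return The input with `speed` (deg/s) and `accel` (deg/s^2) columns.
#' @export
compute_kinematics <- function(samples, sample_rate = 1000) {
  n <- nrow(samples)
  if (n < 5 || sum(complete.cases(samples[, c("x_deg", "y_deg")])) < 5) {
    abort("Kinematics need at least 5 valid samples.",
          class = "stmcit_empty_trace_error")
  }
  dt <- 1 / sample_rate
  vx <- five_point_deriv(samples$x_deg, dt)
  vy <- five_point_deriv(samples$y_deg, dt)
  speed <- sqrt(vx^2 + vy^2)
  accel <- abs(three_point_deriv(speed, dt))
  mutate(samples, speed = speed, accel = accel)
}

five_point_deriv <- function(x, dt) {
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n >= 5) {
    i <- 3:(n - 2)
    d[i] <- (x[i - 2] - 8 * x[i - 1] + 8 * x[i + 1] - x[i + 2]) / (12 * dt)
  }
  d[1] <- (x[2] - x[1]) / dt
  d[2] <- (x[3] - x[1]) / (2 * dt)
  d[n - 1] <- (x[n] - x[n - 2]) / (2 * dt)
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

three_point_deriv <- function(x, dt) {
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (2 * dt)
  }
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Detect blinks as padded runs of invalid samples
#'
#' Maximal runs of invalid samples are padded by `pad_ms` on both sides
#' (clipped to the stream bounds) and merged when the padded intervals
#' overlap.
#'
#' @param samples One stream with `time_ms` and `valid`.
#' @param pad_ms Padding applied to each side, ms.
#' @param sample_rate Sampling rate in Hz.
#' @return Tibble with `onset`, `offset` (ms), possibly empty.
#' @export
detect_blinks <- function(samples, pad_ms = 50, sample_rate = 1000) {
  dt <- 1000 / sample_rate
  if (nrow(samples) == 0 || all(samples$valid)) {
    return(tibble(onset = numeric(0), offset = numeric(0)))
  }
  t0 <- samples$time_ms[1]
  t_end <- samples$time_ms[nrow(samples)] + dt
  ids <- run_length_ids(samples$valid)
  runs <- tibble(id = ids, time_ms = samples$time_ms, valid = samples$valid) |>
    filter(!.data$valid) |>
    group_by(.data$id) |>
    summarise(onset = min(.data$time_ms), offset = max(.data$time_ms) + dt) |>
    mutate(
      onset = pmax(.data$onset - pad_ms, t0),
      offset = pmin(.data$offset + pad_ms, t_end)
    ) |>
    arrange(.data$onset)
  merge_intervals(select(runs, "onset", "offset"))
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(as_tibble(iv))
  onset <- iv$onset
  offset <- iv$offset
  keep_on <- onset[1]
  out_on <- numeric(0)
  out_off <- numeric(0)
  cur_off <- offset[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (onset[i] <= cur_off) {
      cur_off <- max(cur_off, offset[i])
    } else {
      out_on <- c(out_on, keep_on)
      out_off <- c(out_off, cur_off)
      keep_on <- onset[i]
      cur_off <- offset[i]
    }
  }
  tibble(onset = c(out_on, keep_on), offset = c(out_off, cur_off))
}

#' Detect saccades by velocity/acceleration thresholding
#'
#' A saccade is a maximal run of samples whose speed exceeds
#' `vel_thresh` or whose acceleration magnitude exceeds `acc_thresh`
#' (the standard vendor-parser thresholds of 30 deg/s and 8,000 deg/s^2
#' by default), lasting at least `min_dur_ms`. Samples inside blink
#' intervals are never part of a saccade.
#'
#' @param samples One stream with `time_ms`, `x_deg`, `y_deg`, `valid`.
#' @param vel_thresh Velocity threshold, deg/s.
#' @param acc_thresh Acceleration threshold, deg/s^2.
#' @param min_dur_ms Minimum saccade duration, ms.
#' @param blinks Blink intervals from [detect_blinks()].
#' @param sample_rate Sampling rate in Hz.
#' @return Tibble with `onset`, `offset`, `duration`, `x_start`,
#'   `y_start`, `x_end`, `y_end`, `amplitude`.
#' @export
detect_saccades <- function(samples, vel_thresh = 30, acc_thresh = 8000,
                            min_dur_ms = 4, blinks = detect_blinks(samples),
                            sample_rate = 1000) {
  dt <- 1000 / sample_rate
  kin <- compute_kinematics(samples, sample_rate)
  flag <- (kin$speed > vel_thresh | kin$accel > acc_thresh)
  flag[is.na(flag)] <- FALSE
  flag[in_any_interval(samples$time_ms, blinks)] <- FALSE
  ids <- run_length_ids(flag)
  if (!any(flag)) {
    return(tibble(
      onset = numeric(0), offset = numeric(0), duration = numeric(0),
      x_start = numeric(0), y_start = numeric(0),
      x_end = numeric(0), y_end = numeric(0), amplitude = numeric(0)
    ))
  }
  # acceleration transients at motion corners extend an OR-run by the
  # stencil width of the differentiator; where the run contains
  # above-velocity-threshold samples, its boundaries are refined to that
  # velocity extent
  fast <- kin$speed > vel_thresh
  fast[is.na(fast)] <- FALSE
  runs <- tibble(
    id = ids, flagged = flag, fast = fast, time_ms = samples$time_ms,
    x = samples$x_deg, y = samples$y_deg
  ) |>
    filter(.data$flagged) |>
    group_by(.data$id) |>
    summarise(
      keep = list(if (any(.data$fast)) which(.data$fast) else
        seq_along(.data$fast)),
      onset = .data$time_ms[.data$keep[[1]][1]],
      offset = .data$time_ms[max(.data$keep[[1]])] + dt,
      x_start = .data$x[.data$keep[[1]][1]],
      y_start = .data$y[.data$keep[[1]][1]],
      x_end = .data$x[max(.data$keep[[1]])],
      y_end = .data$y[max(.data$keep[[1]])]
    ) |>
    select(-"keep") |>
    mutate(
      duration = .data$offset - .data$onset,
      amplitude = sqrt((.data$x_end - .data$x_start)^2 +
                         (.data$y_end - .data$y_start)^2)
    ) |>
    filter(.data$duration >= min_dur_ms) |>
    select("onset", "offset", "duration", "x_start", "y_start",
           "x_end", "y_end", "amplitude")
  runs
}

in_any_interval <- function(t, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(t)))
  idx <- findInterval(t, iv$onset)
  idx > 0 & t < iv$offset[pmax(idx, 1)]
}

#' Segment fixations as the complement of saccades and blinks
#'
#' Intervals between detected saccades and blinks become fixations. Each
#' fixation's centroid is the mean position of its valid samples; the AOI
#' is the picture box containing the centroid (inclusive edges), else
#' `"background"`. Background fixations are retained but flagged
#' `excluded = TRUE` since gaze on the uniform gray background enters no
#' analysis. Zero-length complement intervals are dropped.
#'
#' @param samples One stream.
#' @param saccades From [detect_saccades()].
#' @param blinks From [detect_blinks()].
#' @param geometry A [screen_geometry()].
#' @param display `"parallel"` or `"single"` (selects the AOI boxes).
#' @param sample_rate Sampling rate in Hz.
#' @return Tibble with `onset`, `offset`, `duration`, `cx`, `cy`, `aoi`,
#'   `excluded`.
#' @export
segment_fixations <- function(samples, saccades, blinks,
                              geometry = screen_geometry(),
                              display = c("parallel", "single"),
                              sample_rate = 1000) {
  display <- match.arg(display)
  dt <- 1000 / sample_rate
  t0 <- samples$time_ms[1]
  t_end <- samples$time_ms[nrow(samples)] + dt
  occupied <- merge_intervals(arrange(
    bind_rows(
      select(saccades, "onset", "offset"),
      select(blinks, "onset", "offset")
    ),
    .data$onset
  ))
  if (nrow(occupied) == 0) {
    comp <- tibble(onset = t0, offset = t_end)
  } else {
    starts <- c(t0, occupied$offset)
    ends <- c(occupied$onset, t_end)
    comp <- tibble(onset = starts, offset = ends) |>
      filter(.data$offset > .data$onset)
  }
  if (nrow(comp) == 0) {
    return(tibble(
      onset = numeric(0), offset = numeric(0), duration = numeric(0),
      cx = numeric(0), cy = numeric(0), aoi = character(0),
      excluded = logical(0)
    ))
  }
  idx <- findInterval(samples$time_ms, comp$onset)
  in_comp <- idx > 0 & samples$time_ms < comp$offset[pmax(idx, 1)] &
    samples$valid
  cent <- tibble(
    id = idx[in_comp],
    x = samples$x_deg[in_comp],
    y = samples$y_deg[in_comp]
  ) |>
    group_by(.data$id) |>
    summarise(cx = mean(.data$x), cy = mean(.data$y))
  out <- mutate(comp, id = row_number(), duration = .data$offset - .data$onset)
  out <- left_join(out, cent, by = "id")
  out$aoi <- assign_aoi(out$cx, out$cy, geometry, display)
  out$aoi[is.na(out$aoi)] <- "background"
  out$excluded <- out$aoi == "background"
  select(out, "onset", "offset", "duration", "cx", "cy", "aoi", "excluded")
}

#' Parse a recording's raw samples into gaze events
#'
#' Runs blink detection, saccade detection and fixation segmentation on
#' every trial and display of a recording (or a compatible samples
#' table), returning one tidy events table.
#'
#' @param x A `cit_recording` from [simulate_participant()], or a samples
#'   tibble with columns `trial_index`, `display`, `time_ms`, `x_deg`,
#'   `y_deg`, `valid`.
#' @param geometry A [screen_geometry()].
#' @param vel_thresh,acc_thresh,min_dur_ms,blink_pad_ms Detector
#'   parameters; see [detect_saccades()] and [detect_blinks()].
#' @return A tibble with one row per event: `trial_index`, `display`,
#'   `event` (`fixation`/`saccade`/`blink`), `onset`, `offset`,
#'   `duration`, `cx`, `cy`, `aoi`, `excluded`.
#' @export
#' @examples
#' sched <- generate_schedule(cit_faces(), seed = 1)
#' rec <- simulate_participant(sched, gaze_config(blink_rate = 0), seed = 1)
#' ev <- detect_events(rec)
#' dplyr::count(ev, event)
detect_events <- function(x, geometry = screen_geometry(), vel_thresh = 30,
                          acc_thresh = 8000, min_dur_ms = 4,
                          blink_pad_ms = 50) {
  samples <- if (inherits(x, "cit_recording")) x$samples else x
  rate <- geometry$sample_rate
  groups <- dplyr::group_split(
    group_by(samples, .data$trial_index, .data$display)
  )
  purrr::map_dfr(groups, function(g) {
    display <- g$display[1]
    blinks <- detect_blinks(g, pad_ms = blink_pad_ms, sample_rate = rate)
    saccades <- detect_saccades(g, vel_thresh, acc_thresh, min_dur_ms,
                                blinks, sample_rate = rate)
    fixations <- segment_fixations(g, saccades, blinks, geometry,
                                   display, sample_rate = rate)
    bind_rows(
      mutate(
        select(fixations, "onset", "offset", "duration", "cx", "cy",
               "aoi", "excluded"),
        event = "fixation"
      ),
      mutate(
        select(saccades, "onset", "offset", "duration"),
        event = "saccade", cx = NA_real_, cy = NA_real_,
        aoi = NA_character_, excluded = FALSE
      ),
      mutate(blinks, event = "blink", duration = .data$offset - .data$onset,
             cx = NA_real_, cy = NA_real_, aoi = NA_character_,
             excluded = FALSE)
    ) |>
      mutate(trial_index = g$trial_index[1], display = display) |>
      arrange(.data$onset) |>
      select("trial_index", "display", "event", "onset", "offset",
             "duration", "cx", "cy", "aoi", "excluded")
  })
}
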