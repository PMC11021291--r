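# Table of trial types: presence of a famous face in the parallel and
# single-face displays and the correct answer, with per-experiment counts.
TRIAL_TYPES <- data.frame(
  trial_type = 1:6,
  famous_parallel = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  famous_single = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
  correct_answer = c("yes", "yes", "no", "no", "yes", "no"),
  n_trials = c(16L, 8L, 8L, 16L, 8L, 8L)
)

#' Generate a counterbalanced 64-trial STM-CIT schedule
#'
#' Builds a pseudorandomized schedule of 64 trials under the design
#' constraints of the test: six trial types (16/8/8/16/8/8 trials), all
#' faces within a trial of one gender, each famous face appearing exactly
#' four times in the parallel displays (once per grid location) and four
#' times as the single face, each non-famous face appearing exactly four
#' times in the parallel displays and at most once as the single face, and
#' the correct answer "yes" in half of the trials. In addition every
#' non-famous face is guaranteed at least one appearance in a trial whose
#' parallel display contains no famous face, so that classification
#' features are computable for every face.
#'
#' Generation uses randomized slot assignment with per-face quota counters
#' and bounded restarts; the result is deterministic for a fixed seed.
#'
#' @param faces Face set as returned by [cit_faces()]: 64 rows with
#'   `face_id`, `famous`, `gender`.
#' @param seed Integer seed controlling all randomization.
#' @param max_restarts Bound on internal restarts before giving up.
#' @return A tibble of 64 rows (class `cit_schedule`) with columns
#'   `trial_index`, `trial_type`, `gender`, the four grid locations
#'   (`top_left`, `top_right`, `bottom_left`, `bottom_right`),
#'   `single_face` and `correct_answer`. The face set and seed are kept as
#'   attributes `faces` and `seed`.
#' @seealso [validate_schedule()]
#' @export
#' @examples
#' sched <- generate_schedule(cit_faces(), seed = 1)
#' dplyr::count(sched, trial_type)
generate_schedule <- function(faces = cit_faces(), seed = 1L,
                              max_restarts = 50L) {
  check_face_set(faces)
  withr::with_seed(substream_seed(seed, "schedule"), {
    trials <- NULL
    for (attempt in seq_len(max_restarts)) {
      trials <- tryCatch(
        bind_rows(
          generate_gender_block(faces, "male"),
          generate_gender_block(faces, "female")
        ),
        stmcit_retry = function(e) NULL
      )
      if (!is.null(trials)) break
    }
    if (is.null(trials)) {
      abort(
        paste0("Schedule generation failed after ", max_restarts, " restarts."),
        class = "stmcit_retry_exhausted"
      )
    }
    trials <- trials[sample.int(nrow(trials)), ]
    trials$trial_index <- seq_len(nrow(trials))
    trials <- select(
      trials, "trial_index", "trial_type", "gender",
      dplyr::all_of(GRID_LOCATIONS), "single_face", "correct_answer"
    )
    structure(
      as_tibble(trials),
      faces = faces,
      seed = as.integer(seed),
      class = c("cit_schedule", class(as_tibble(trials)))
    )
  })
}

# One gender's 32 trials (types 8/4/4/8/4/4); raises condition class
# "stmcit_retry" on a randomization dead end so the caller can restart.
generate_gender_block <- function(faces, gender) {
  fg <- faces[faces$gender == gender, ]
  famous_ids <- fg$face_id[fg$famous]
  unknown_ids <- fg$face_id[!fg$famous]
  types <- rep(1:6, c(8L, 4L, 4L, 8L, 4L, 4L))
  n_trials <- length(types)
  parallel <- matrix(NA_character_, nrow = n_trials, ncol = 4,
                     dimnames = list(NULL, GRID_LOCATIONS))

  # Famous parallel slots: each famous face once per grid location,
  # its four appearances spread over the 16 famous-parallel trials.
  fam_trials <- which(types %in% 1:3)
  pair_face <- rep(famous_ids, each = 4)
  pair_loc <- unlist(lapply(famous_ids, function(f) sample(GRID_LOCATIONS)))
  ord <- sample.int(length(pair_face))
  fam_of_trial <- character(n_trials)
  for (k in seq_along(fam_trials)) {
    tr <- fam_trials[k]
    parallel[tr, pair_loc[ord[k]]] <- pair_face[ord[k]]
    fam_of_trial[tr] <- pair_face[ord[k]]
  }

  # Famous single-face quota: 4 appearances per famous face, split between
  # its type-1 trials (where it is also on display) and type-4 trials.
  t1_count <- table(factor(fam_of_trial[types == 1], levels = famous_ids))
  need_t4 <- 4L - as.integer(t1_count)
  if (any(need_t4 < 0)) abort("quota dead end", class = "stmcit_retry")
  t4_faces <- sample(rep(famous_ids, need_t4))
  single <- character(n_trials)
  single[types == 1] <- fam_of_trial[types == 1]
  single[types == 4] <- t4_faces

  # Non-famous parallel slots: quota of exactly 4 per face. Pass 1 places
  # each face once in a no-famous trial (coverage guarantee); pass 2 fills
  # the rest by quota-weighted sampling without within-trial repeats.
  quota <- stats::setNames(rep(4L, length(unknown_ids)), unknown_ids)
  open_nofam <- which(types %in% 4:6)
  openings <- expand.grid(trial = open_nofam, loc = GRID_LOCATIONS,
                          stringsAsFactors = FALSE)
  openings <- openings[sample.int(nrow(openings)), ]
  for (i in seq_along(unknown_ids)) {
    parallel[openings$trial[i], openings$loc[i]] <- unknown_ids[i]
  }
  quota[unknown_ids] <- quota[unknown_ids] - 1L
  for (tr in sample.int(n_trials)) {
    fill <- GRID_LOCATIONS[is.na(parallel[tr, ])]
    for (loc in fill) {
      in_trial <- stats::na.omit(parallel[tr, ])
      avail <- names(quota)[quota > 0 & !(names(quota) %in% in_trial)]
      if (length(avail) == 0) abort("fill dead end", class = "stmcit_retry")
      pick <- if (length(avail) == 1) avail else {
        sample(avail, 1, prob = quota[avail])
      }
      parallel[tr, loc] <- pick
      quota[pick] <- quota[pick] - 1L
    }
  }
  if (any(quota != 0)) abort("quota dead end", class = "stmcit_retry")

  # Non-famous single faces: at most once each; types 2/5 reuse a face from
  # the trial's own parallel display, types 3/6 use a novel same-gender face.
  used_single <- character(0)
  for (tr in sample(which(types %in% c(2L, 5L)))) {
    pool <- setdiff(stats::na.omit(parallel[tr, ]), c(famous_ids, used_single))
    if (length(pool) == 0) abort("single dead end", class = "stmcit_retry")
    single[tr] <- if (length(pool) == 1) pool else sample(pool, 1)
    used_single <- c(used_single, single[tr])
  }
  for (tr in sample(which(types %in% c(3L, 6L)))) {
    pool <- setdiff(unknown_ids, c(parallel[tr, ], used_single))
    if (length(pool) == 0) abort("single dead end", class = "stmcit_retry")
    single[tr] <- if (length(pool) == 1) pool else sample(pool, 1)
    used_single <- c(used_single, single[tr])
  }

  tibble(
    trial_type = types,
    gender = gender,
    top_left = parallel[, "top_left"],
    top_right = parallel[, "top_right"],
    bottom_left = parallel[, "bottom_left"],
    bottom_right = parallel[, "bottom_right"],
    single_face = single,
    correct_answer = TRIAL_TYPES$correct_answer[types]
  )
}

#' Pivot a schedule to one row per parallel-display face
#'
#' @param schedule A `cit_schedule` (or compatible data frame).
#' @return A tibble with columns `trial_index`, `trial_type`, `gender`,
#'   `location`, `face_id`.
#' @export
schedule_long <- function(schedule) {
  tidyr::pivot_longer(
    select(schedule, "trial_index", "trial_type", "gender",
           dplyr::all_of(GRID_LOCATIONS)),
    cols = dplyr::all_of(GRID_LOCATIONS),
    names_to = "location", values_to = "face_id"
  )
}

#' Validate an STM-CIT schedule against all design constraints
#'
#' Runs every named design constraint against a schedule and reports each
#' as pass/fail with the offending trial indices. A schedule produced by
#' [generate_schedule()] passes all checks.
#'
#' @param schedule A `cit_schedule` or a data frame with the same columns.
#' @param faces The face set the schedule was built from; defaults to the
#'   `faces` attribute of `schedule`.
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
#' @examples
#' report <- validate_schedule(generate_schedule(cit_faces(), seed = 7))
#' all(report$pass)
validate_schedule <- function(schedule, faces = attr(schedule, "faces")) {
  required <- c("trial_index", "trial_type", "gender", GRID_LOCATIONS,
                "single_face", "correct_answer")
  missing <- setdiff(required, names(schedule))
  if (length(missing) > 0) {
    abort(
      paste0("Malformed schedule: missing field(s) ",
             paste(missing, collapse = ", ")),
      class = "stmcit_parse_error"
    )
  }
  if (is.null(faces)) faces <- cit_faces()
  check_face_set(faces)
  fame <- stats::setNames(faces$famous, faces$face_id)
  face_gender <- stats::setNames(faces$gender, faces$face_id)
  long <- schedule_long(schedule)
  par_mat <- as.matrix(schedule[, GRID_LOCATIONS])

  checks <- list()
  add <- function(name, bad_trials, note = NULL) {
    pass <- length(bad_trials) == 0
    detail <- if (pass) {
      "ok"
    } else if (!is.null(note)) {
      note
    } else {
      paste0("trials: ", paste(sort(unique(bad_trials)), collapse = ","))
    }
    checks[[name]] <<- tibble(check = name, pass = pass, detail = detail)
  }

  counts <- table(factor(schedule$trial_type, levels = 1:6))
  add("type_counts", if (!all(counts == TRIAL_TYPES$n_trials)) 0L else integer(0),
      paste0("counts ", paste(counts, collapse = "/")))
  add("yes_answer_count",
      if (sum(schedule$correct_answer == "yes") != 32) 0L else integer(0),
      paste0(sum(schedule$correct_answer == "yes"), " yes answers"))

  dup <- apply(par_mat, 1, anyDuplicated) > 0
  add("parallel_faces_distinct", schedule$trial_index[dup])

  bad_gender <- face_gender[long$face_id] != long$gender
  bad_single_gender <- face_gender[schedule$single_face] != schedule$gender
  add("gender_consistency",
      c(long$trial_index[bad_gender],
        schedule$trial_index[bad_single_gender]))

  fam_in_par <- apply(par_mat, 1, function(r) any(fame[r]))
  fam_single <- unname(fame[schedule$single_face])
  tt <- TRIAL_TYPES[schedule$trial_type, ]
  add("type_consistency",
      schedule$trial_index[fam_in_par != tt$famous_parallel |
                             fam_single != tt$famous_single |
                             schedule$correct_answer != tt$correct_answer])

  in_par <- vapply(seq_len(nrow(schedule)),
                   function(i) schedule$single_face[i] %in% par_mat[i, ],
                   logical(1))
  add("answer_consistency",
      schedule$trial_index[(schedule$correct_answer == "yes") != in_par])

  fam_long <- long[fame[long$face_id], ]
  fam_app <- table(factor(fam_long$face_id, levels = faces$face_id[faces$famous]))
  fam_loc <- table(factor(fam_long$face_id, levels = faces$face_id[faces$famous]),
                   factor(fam_long$location, levels = GRID_LOCATIONS))
  add("famous_parallel_quota",
      if (!all(fam_app == 4) || !all(fam_loc == 1)) 0L else integer(0),
      "a famous face misses the 4-appearances / once-per-location quota")
  fam_single_counts <- table(factor(schedule$single_face[fam_single],
                                    levels = faces$face_id[faces$famous]))
  add("famous_single_quota",
      if (!all(fam_single_counts == 4)) 0L else integer(0),
      "a famous face is not the single face exactly 4 times")

  unk_ids <- faces$face_id[!faces$famous]
  unk_app <- table(factor(long$face_id[!fame[long$face_id]], levels = unk_ids))
  add("nonfamous_parallel_quota",
      if (!all(unk_app == 4)) 0L else integer(0),
      "a non-famous face does not appear exactly 4 times in parallel displays")
  unk_single_counts <- table(factor(schedule$single_face[!fam_single],
                                    levels = unk_ids))
  add("nonfamous_single_at_most_once",
      if (any(unk_single_counts > 1)) 0L else integer(0),
      "a non-famous face is the single face more than once")

  nofam_trials <- long$trial_index %in% schedule$trial_index[!fam_in_par]
  covered <- unique(long$face_id[nofam_trials])
  add("nonfamous_nofamous_coverage",
      if (!all(unk_ids %in% covered)) 0L else integer(0),
      "a non-famous face never appears in a no-famous-face trial")

  gender_counts <- table(factor(schedule$gender, levels = c("male", "female")))
  per_gender <- table(schedule$gender, factor(schedule$trial_type, levels = 1:6))
  balanced <- all(gender_counts == 32) &&
    all(per_gender["male", ] == c(8, 4, 4, 8, 4, 4)) &&
    all(per_gender["female", ] == c(8, 4, 4, 8, 4, 4))
  add("gender_balance", if (!balanced) 0L else integer(0),
      "trial genders are not balanced 32/32 with per-gender type counts 8/4/4/8/4/4")

  bind_rows(checks)
}
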