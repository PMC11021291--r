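#' Apply post-test misidentification relabeling and trial exclusions
#'
#' Faces are relabeled by the participant's post-test judgments: an
#' unknown face judged famous (false recognition) becomes effectively
#' familiar; a famous face not recognized (miss) becomes effectively
#' non-familiar. Trials whose parallel display contains more than one
#' false recognition, or one celebrity face together with a false
#' recognition, are flagged for exclusion. In strict mode every trial
#' containing any misidentified face (false recognition or miss) is
#' excluded instead.
#'
#' @param schedule A [generate_schedule()] result.
#' @param posttest Tibble with `face_id` and `judged_famous` covering all
#'   64 faces.
#' @param strict Exclude all trials containing any misidentified face.
#' @return A list of class `cit_labels`: `labels` (tibble `face_id`,
#'   `famous`, `judged_famous`, `familiar`), and `trials` (tibble
#'   `trial_index`, `n_familiar`, `include`, `reason`).
#' @export
#' @examples
#' sched <- generate_schedule(cit_faces(), seed = 1)
#' pt <- tibble::tibble(face_id = cit_faces()$face_id,
#'                      judged_famous = cit_faces()$famous)
#' lab <- apply_misidentification(sched, pt)
#' all(lab$trials$include)
apply_misidentification <- function(schedule, posttest, strict = FALSE) {
  faces <- attr(schedule, "faces") %||% cit_faces()
  missing <- setdiff(faces$face_id, posttest$face_id)
  if (length(missing) > 0) {
    abort(
      paste0("Post-test is missing face(s): ",
             paste(head(missing, 5), collapse = ", ")),
      class = "stmcit_data_error"
    )
  }
  labels <- left_join(faces, select(posttest, "face_id", "judged_famous"),
                      by = "face_id") |>
    mutate(familiar = .data$judged_famous)

  status <- stats::setNames(
    dplyr::case_when(
      !labels$famous & labels$judged_famous ~ "false_recognition",
      labels$famous & !labels$judged_famous ~ "miss",
      TRUE ~ "correct"
    ),
    labels$face_id
  )
  familiar <- stats::setNames(labels$familiar, labels$face_id)
  fame <- stats::setNames(labels$famous, labels$face_id)

  par_mat <- as.matrix(schedule[, GRID_LOCATIONS])
  n_false <- rowSums(matrix(status[par_mat] == "false_recognition",
                            nrow = nrow(schedule)))
  n_miss <- rowSums(matrix(status[par_mat] == "miss", nrow = nrow(schedule)))
  n_celeb <- rowSums(matrix(fame[par_mat], nrow = nrow(schedule)))
  n_familiar <- rowSums(matrix(familiar[par_mat], nrow = nrow(schedule)))

  reason <- dplyr::case_when(
    n_false > 1 ~ ">1 false recognition in parallel display",
    n_celeb >= 1 & n_false >= 1 ~ "celebrity + false recognition in parallel display",
    strict & (n_false + n_miss) >= 1 ~ "contains misidentified face (strict)",
    TRUE ~ "none"
  )
  structure(
    list(
      labels = select(labels, "face_id", "famous", "judged_famous",
                      "familiar"),
      trials = tibble(
        trial_index = schedule$trial_index,
        n_familiar = as.integer(n_familiar),
        include = reason == "none",
        reason = reason
      )
    ),
    class = "cit_labels"
  )
}
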