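#' Read and write STM-CIT schedules
#'
#' Schedules serialize losslessly to JSON (one object per trial with
#' explicit grid-location keys, plus the face set and seed) and to a flat
#' CSV dialect (one row per trial). JSON carries the face set; when
#' reading CSV, supply `faces` if the schedule was built from a
#' non-default set.
#'
#' @param schedule A `cit_schedule`.
#' @param path File path.
#' @param faces Face set to attach when reading CSV.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   `cit_schedule`.
#' @name schedule_io
NULL

#' @rdname schedule_io
#' @export
write_schedule_json <- function(schedule, path) {
  payload <- list(
    seed = attr(schedule, "seed"),
    faces = as.data.frame(attr(schedule, "faces") %||% cit_faces()),
    trials = lapply(seq_len(nrow(schedule)), function(i) {
      row <- schedule[i, ]
      list(
        trial_index = row$trial_index,
        trial_type = row$trial_type,
        gender = row$gender,
        parallel = as.list(row[GRID_LOCATIONS]),
        single_face = row$single_face,
        correct_answer = row$correct_answer
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  trials <- purrr::map_dfr(payload$trials, function(tr) {
    tibble(
      trial_index = as.integer(tr$trial_index),
      trial_type = as.integer(tr$trial_type),
      gender = tr$gender,
      top_left = tr$parallel$top_left,
      top_right = tr$parallel$top_right,
      bottom_left = tr$parallel$bottom_left,
      bottom_right = tr$parallel$bottom_right,
      single_face = tr$single_face,
      correct_answer = tr$correct_answer
    )
  })
  faces <- as_tibble(purrr::map_dfr(payload$faces, as_tibble))
  faces$famous <- as.logical(faces$famous)
  structure(
    trials,
    faces = faces,
    seed = as.integer(payload$seed %||% NA_integer_),
    class = c("cit_schedule", class(trials))
  )
}

#' @rdname schedule_io
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule_csv <- function(path, faces = cit_faces()) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  df$trial_index <- as.integer(df$trial_index)
  df$trial_type <- as.integer(df$trial_type)
  structure(
    df,
    faces = faces,
    class = c("cit_schedule", class(df))
  )
}
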