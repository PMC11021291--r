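#' Default STM-CIT face set
#'
#' The test uses 64 face pictures: 8 famous (4 per gender) and 56 unknown
#' (28 per gender). Only identifiers are scheduled; no image handling is
#' performed. Identifiers encode fame and gender for readability
#' (e.g. `"fam_m1"`, `"unk_f12"`) but all downstream code uses the
#' `famous` and `gender` columns, never the identifier text.
#'
#' @return A tibble with columns `face_id` (character), `famous` (logical)
#'   and `gender` (`"male"`/`"female"`), 64 rows.
#' @export
#' @examples
#' faces <- cit_faces()
#' dplyr::count(faces, famous, gender)
cit_faces <- function() {
  tibble(
    face_id = c(
      paste0("fam_m", 1:4), paste0("fam_f", 1:4),
      paste0("unk_m", 1:28), paste0("unk_f", 1:28)
    ),
    famous = rep(c(TRUE, FALSE), c(8, 56)),
    gender = c(
      rep(c("male", "female"), each = 4),
      rep(c("male", "female"), each = 28)
    )
  )
}

check_face_set <- function(faces) {
  if (!is.data.frame(faces)) {
    abort("`faces` must be a data frame.", class = "stmcit_config_error")
  }
  required <- c("face_id", "famous", "gender")
  missing <- setdiff(required, names(faces))
  if (length(missing) > 0) {
    abort(
      paste0("`faces` is missing column(s): ", paste(missing, collapse = ", ")),
      class = "stmcit_config_error"
    )
  }
  if (anyDuplicated(faces$face_id)) {
    abort("`faces$face_id` must be unique.", class = "stmcit_config_error")
  }
  tab <- table(faces$famous, faces$gender)
  ok <- nrow(faces) == 64 &&
    all(sort(unique(faces$gender)) == c("female", "male")) &&
    all(tab["TRUE", c("male", "female")] == c(4, 4)) &&
    all(tab["FALSE", c("male", "female")] == c(28, 28))
  if (!ok) {
    abort(
      paste0(
        "Face set must contain exactly 64 faces: 8 famous (4 per gender) ",
        "and 56 non-famous (28 per gender)."
      ),
      class = "stmcit_config_error"
    )
  }
  invisible(faces)
}
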