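#' Screen and AOI geometry of the STM-CIT display
#'
#' The parallel display shows four face pictures of 11.5 degrees (height)
#' by 8.6 degrees (width) whose centers sit on the screen diagonals at 18
#' degrees of eccentricity from screen center; the single-face display
#' shows one picture of the same size at screen center. Coordinates are
#' screen-centered degrees of visual angle, x rightward, y upward.
#'
#' @param picture_height,picture_width Picture size in degrees.
#' @param center_eccentricity Eccentricity of the four picture centers
#'   along the diagonals, degrees.
#' @param sample_rate Gaze sampling rate in Hz.
#' @return A list of class `cit_geometry` with the parameters and a
#'   precomputed `boxes` tibble (one row per AOI: the four grid locations
#'   plus `single`), giving centers and inclusive box edges.
#' @export
#' @examples
#' screen_geometry()$boxes
screen_geometry <- function(picture_height = 11.5, picture_width = 8.6,
                            center_eccentricity = 18, sample_rate = 1000) {
  stopifnot(picture_height > 0, picture_width > 0,
            center_eccentricity > 0, sample_rate > 0)
  d <- center_eccentricity / sqrt(2)
  centers <- tibble(
    aoi = c(GRID_LOCATIONS, "single"),
    cx = c(-d, d, -d, d, 0),
    cy = c(d, d, -d, -d, 0)
  )
  boxes <- mutate(
    centers,
    xmin = .data$cx - picture_width / 2,
    xmax = .data$cx + picture_width / 2,
    ymin = .data$cy - picture_height / 2,
    ymax = .data$cy + picture_height / 2
  )
  # the four pictures must not overlap each other or the central picture
  gap_x <- 2 * d - picture_width
  gap_y <- 2 * d - picture_height
  if (gap_x <= 0 || gap_y <= 0) {
    abort("AOI boxes overlap for this geometry.",
          class = "stmcit_config_error")
  }
  structure(
    list(
      picture_height = picture_height,
      picture_width = picture_width,
      center_eccentricity = center_eccentricity,
      sample_rate = sample_rate,
      boxes = boxes
    ),
    class = "cit_geometry"
  )
}

#' Assign gaze points to areas of interest
#'
#' Points on a box edge belong to that box (inclusive edges); points in no
#' box are `"background"`. `NA` positions give `NA`.
#'
#' @param x,y Positions in screen-centered degrees.
#' @param geometry A [screen_geometry()].
#' @param display `"parallel"` (four face boxes) or `"single"` (the
#'   central box).
#' @return Character vector of AOI labels.
#' @export
assign_aoi <- function(x, y, geometry = screen_geometry(),
                       display = c("parallel", "single")) {
  display <- match.arg(display)
  boxes <- geometry$boxes
  boxes <- if (display == "parallel") {
    boxes[boxes$aoi != "single", ]
  } else {
    boxes[boxes$aoi == "single", ]
  }
  out <- rep(NA_character_, length(x))
  known <- !is.na(x) & !is.na(y)
  out[known] <- "background"
  for (i in seq_len(nrow(boxes))) {
    hit <- known & x >= boxes$xmin[i] & x <= boxes$xmax[i] &
      y >= boxes$ymin[i] & y <= boxes$ymax[i]
    out[hit] <- boxes$aoi[i]
  }
  out
}
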