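#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across count pull rename if_else row_number
#' @importFrom stats rnorm runif rlnorm rbinom rpois sd qnorm shapiro.test
#'   t.test wilcox.test aov pf approx complete.cases
#' @importFrom utils head tail
NULL

# Overlap length of interval [a, b) with window [w1, w2)
interval_overlap <- function(a, b, w1, w2) {
  pmax(0, pmin(b, w2) - pmax(a, w1))
}

#' Derive a stage-specific random seed from a master seed
#'
#' Expands one master seed into reproducible per-stage substreams so that
#' pipeline stages (schedule generation, simulation, classification, ...)
#' can be rerun independently while staying tied to a single seed.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character) or integer offset.
#' @param index Optional extra index (e.g., participant number).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stage, index = 0L) {
  stage_num <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.numeric(stage)
  }
  # double-precision modular hash; all operands well below 2^53
  x <- (as.numeric(seed) * 48271 + stage_num * 16807 + as.numeric(index) * 69621) %% 2147483647
  as.integer(x)
}

run_length_ids <- function(x) {
  # integer id per maximal run of equal values (NA-safe for logicals)
  if (length(x) == 0) return(integer(0))
  changed <- c(TRUE, x[-1] != x[-length(x)])
  cumsum(changed)
}
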