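#' Read and write generator configurations as YAML
#'
#' Every [gaze_config()] field round-trips through a flat YAML mapping;
#' unknown keys are rejected by the constructor's validation.
#'
#' @param config A [gaze_config()].
#' @param path YAML file path.
#' @return `write_gaze_config()` returns `path` invisibly;
#'   `read_gaze_config()` returns a validated `cit_gaze_config`.
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_gaze_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The 'yaml' package is required for YAML configs.")
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_gaze_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The 'yaml' package is required for YAML configs.")
  }
  fields <- yaml::read_yaml(path)
  do.call(gaze_config, fields)
}

#' Run the pipeline from a YAML configuration bundle
#'
#' The bundle holds `seed`, `n_participants`, `out_dir`, optional
#' `strict`/`between` flags and a `groups` mapping of group name to
#' [gaze_config()] fields.
#'
#' @param path YAML bundle path.
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The 'yaml' package is required for YAML configs.")
  }
  bundle <- yaml::read_yaml(path)
  groups <- lapply(bundle$groups %||% list(control = list()),
                   function(fields) do.call(gaze_config, fields))
  run_pipeline(
    out_dir = bundle$out_dir %||% ".",
    seed = as.integer(bundle$seed %||% 1L),
    groups = groups,
    n_participants = bundle$n_participants %||% 15,
    strict = isTRUE(bundle$strict),
    between = isTRUE(bundle$between)
  )
}
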