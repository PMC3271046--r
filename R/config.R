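#' Configuration handling
#'
#' Settings are layered: built-in defaults, overridden by a YAML config
#' file, overridden by command-line flags. [default_config()] documents
#' every default in one place.
#'
#' @name config
NULL

#' Built-in default configuration
#'
#' @return A nested list: `fps` (25), `dct` (`magnitude_threshold` 20,
#'   `decision_threshold` 0.5, `working_size` 256), `branch`
#'   (`dark_threshold` 40, `se_radius` 5, `min_area_fraction` 0.01),
#'   `summary` (`ratio` 12, `min_summary_seconds` 30, `pad_frames` 12,
#'   `merge_gap_frames` 12).
#' @export
default_config <- function() {
  list(
    fps = 25,
    dct = list(magnitude_threshold = 20, decision_threshold = 0.5,
               working_size = 256L),
    branch = list(dark_threshold = 40, se_radius = 5L,
                  min_area_fraction = 0.01),
    summary = list(ratio = 12, min_summary_seconds = 30, pad_frames = 12L,
                   merge_gap_frames = 12L))
}

#' Load a layered run configuration
#'
#' @param path Optional YAML file with any subset of the
#'   [default_config()] keys.
#' @param overrides Optional named nested list applied last (command-line
#'   flags).
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    file_cfg <- yaml::read_yaml(path)
    if (!is.null(file_cfg)) cfg <- modifyList(cfg, file_cfg)
  }
  modifyList(cfg, overrides)
}

config_objects <- function(cfg) {
  list(
    dct = dct_detector(cfg$dct$magnitude_threshold,
                       cfg$dct$decision_threshold, cfg$dct$working_size),
    branch = branch_params(cfg$branch$dark_threshold, cfg$branch$se_radius,
                           cfg$branch$min_area_fraction),
    summary = summary_config(cfg$summary$ratio,
                             cfg$summary$min_summary_seconds,
                             cfg$summary$pad_frames,
                             cfg$summary$merge_gap_frames))
}
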