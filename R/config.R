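#' Pipeline run configuration
#'
#' Collects every stage parameter with its default; defaults follow the
#' source protocols where those state a value (3-frame smoothing, 10-value
#' minimum baseline, 10 s SOCE window, 300 s sustained offset, 180 s track
#' filter, 4 um maximum jump with 10-frame disturbance, 0.5-ratio bins,
#' 10 um/min fast threshold, 8 um process filter).  The object round-trips
#' losslessly through YAML via [read_run_config()] / [write_run_config()].
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    traces = list(smooth_window = 3L, baseline_k = 10L, peak_window = 120,
                  response_offset = 300, soce_window = 10, responder_n_sd = 3,
                  responder_floor = 0.05, stim_time = NULL, readd_time = NULL,
                  background_green = 0, background_red = 0),
    motility = list(min_duration = 180, max_lag_fraction = 0.5,
                    pixel_size = NULL),
    linking = list(max_jump = 4, max_missing_frames = 10L),
    coupling = list(bin_width = 0.5, fast_threshold = 10,
                    align_tolerance = NULL),
    morphology = list(threshold = 100, pixel_size = 0.5,
                      min_process_length = 8, area_max = 4L, spur_min_px = 3L),
    io = list(input_traces = NULL, input_tracks = NULL, input_fields = NULL,
              output_dir = "mgca-output"),
    stages = character(0))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) {
    abort(sprintf("unknown config section(s): %s.", paste(bad, collapse = ", ")),
          class = "mgca_parameter_error")
  }
  # merge that keeps explicit NULLs (e.g. an unset stim_time stays a key)
  merge_keep_null <- function(def, over) {
    for (nm in names(over)) def[nm] <- list(over[[nm]])
    def
  }
  cfg <- defaults
  for (nm in names(overrides)) {
    cfg[nm] <- list(
      if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
          !is.null(names(defaults[[nm]]))) {
        merge_keep_null(defaults[[nm]], overrides[[nm]])
      } else {
        overrides[[nm]]
      })
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable short hash of a config (FNV-1a over the deparsed object).  Paths
# are excluded so the hash identifies the analysis parameters, not where the
# files happen to live.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$io <- NULL
  s <- paste(deparse(cfg), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647  # polynomial rolling hash
  sprintf("%08x", h)
}
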