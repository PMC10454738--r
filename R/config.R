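#' Default pipeline configuration
#'
#' Scan parameters follow the study settings (maximum PQS length 45 nt,
#' minimum G-group 3, loop lengths 1-14, G-score threshold 60); evidence and
#' localization thresholds carry their documented defaults. All thresholds are
#' finite and the seed is a non-negative integer.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    max_length = 45L, min_g_group = 3L, loop_min = 1L, loop_max = 14L,
    score_threshold = 60L,
    rpi_threshold = 0.5, rpi_mode = "both",
    pseudocount = 0.01, neutral_band = 0.5,
    seed = 1L, log_level = "info"
  )
}

#' Read a flat key-value configuration file (YAML)
#'
#' Unknown keys are rejected; values given in the file override the defaults,
#' mirroring how command-line flags override the config in the CLI.
#'
#' @param path YAML file path, or NULL for defaults.
#' @param overrides named list applied on top of the file values.
#' @return full configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown)) {
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    cfg[names(vals)] <- vals
  }
  cfg[names(overrides)] <- overrides
  num <- c("max_length", "min_g_group", "loop_min", "loop_max", "score_threshold",
           "rpi_threshold", "pseudocount", "neutral_band", "seed")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || !is.finite(cfg[[k]])) {
      stop(sprintf("config value '%s' must be finite numeric", k), call. = FALSE)
    }
  }
  if (cfg$seed < 0 || cfg$seed != as.integer(cfg$seed)) {
    stop("config 'seed' must be a non-negative integer", call. = FALSE)
  }
  cfg
}

# Stage logging in "records in -> records out" form, so the funnel shape of a
# screening run is reproducible on user data. Silenced when
# options(qgrscan.quiet = TRUE).
qgr_log <- function(stage, n_in, n_out) {
  if (isTRUE(getOption("qgrscan.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %d records in -> %d records out", stage, n_in, n_out))
  invisible(NULL)
}
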