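# Shared YAML pipeline configuration consumed by the command-line interface
# and convenient for scripted runs.

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema: `cohort` ([cohort_config()]
#' arguments), `staple` ([staple_params()] arguments), `margins_mm`, and
#' `calibration` (target mean translation distance, tolerance, search
#' radius).
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    cohort = list(n_patients = 15L, shape = c(24L, 96L, 96L),
                  spacing_mm = c(2.5, 1, 1),
                  lesion_volume_range_ml = c(0.22, 11.22),
                  n_observers = 4L,
                  boundary_noise_mm = 0.5,
                  misregistration_sd_mm = 1.7 / sqrt(pi / 2),
                  gleason4or5_fraction = 0.85, seed = 1L),
    staple = list(threshold = 0.95, max_iterations = 200L, tolerance = 1e-7,
                  prior_mode = "global_fraction"),
    margins_mm = c(0, 1, 2, 3),
    calibration = list(target_mean_mm = 1.7, tolerance_mm = 0.01,
                       search_radius_mm = 10))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; everything else keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_cfg(cfg, user)
  cfg$margins_mm <- as.numeric(unlist(cfg$margins_mm))
  cfg
}

# YAML sequences of mixed int/double arrive as lists; flatten scalars-only
# lists to plain vectors (recursively, so per-modality range lists survive)
flatten_yaml <- function(x) {
  if (!is.list(x)) return(x)
  if (all(vapply(x, function(e) is.atomic(e) && length(e) == 1L, logical(1L))) &&
      is.null(names(x)))
    return(unlist(x))
  lapply(x, flatten_yaml)
}

# materialize the parameter objects from a configuration list
config_staple_params <- function(cfg) do.call(staple_params,
                                              flatten_yaml(cfg$staple))
config_cohort <- function(cfg) do.call(cohort_config,
                                       flatten_yaml(cfg$cohort))
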