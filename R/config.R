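#' Run configuration with validated defaults
#'
#' Central tunables of the pipeline with their standard defaults: LNCC
#' window `sigma_g = 2` voxels, rank-decay `beta = 0.5`, pooled top size
#' `T = 7`, refined mask-fusion threshold 0.8, affine-stage fusion threshold
#' 0.5, and the two-stage registration block. Unknown keys are rejected and
#' all range violations are reported at once.
#'
#' @param ... overrides for any default field.
#' @return A validated list of class `vx_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    sigma_g = 2,
    beta = 0.5,
    T = 7,
    majority_threshold = NA,    # NA = ceil(T/2 + 1)
    fusion_threshold = 0.8,
    affine_fusion_threshold = 0.5,
    closing_radius = 3,
    min_component_voxels = 100,
    registration = list(backend = "identity",
                        rigid_levels = 3, rigid_iterations = 5,
                        affine_levels = 3, affine_iterations = 8,
                        nonrigid_levels = 3, nonrigid_iterations = 300,
                        bending_energy = 0.005, nonrigid_metric = "NMI",
                        external_command = NULL),
    seed = 1
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$sigma_g) && cfg$sigma_g > 0, "sigma_g must be > 0")
  chk(is.numeric(cfg$beta) && cfg$beta > 0, "beta must be > 0")
  chk(is.numeric(cfg$T) && cfg$T >= 1 && cfg$T == round(cfg$T),
      "T must be an integer >= 1")
  chk(cfg$fusion_threshold > 0 && cfg$fusion_threshold <= 1,
      "fusion_threshold must be in (0, 1]")
  chk(cfg$affine_fusion_threshold > 0 && cfg$affine_fusion_threshold <= 1,
      "affine_fusion_threshold must be in (0, 1]")
  chk(cfg$closing_radius >= 0, "closing_radius must be >= 0")
  chk(cfg$min_component_voxels >= 1, "min_component_voxels must be >= 1")
  chk(is.na(cfg$majority_threshold) ||
        (cfg$majority_threshold >= 1 && cfg$majority_threshold <= cfg$T),
      "majority_threshold must be in [1, T] (or NA for the default)")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  if (is.numeric(cfg$T) && cfg$T %% 2 == 0)
    warning("even T: exact top-T splits cannot reach an absolute majority as",
            " easily; odd T recommended")
  structure(cfg, class = "vx_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys are
#'   [run_config()] fields.
#' @return A validated `vx_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  do.call(run_config, list(raw))
}
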