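#' List available scenario presets
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "chemodegen")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Load a scenario preset
#'
#' Presets encode the cultivation conditions and calibrated strain
#' parameters of the six cultivations summarised in the study's overview
#' table (`chemostat-1` .. `chemostat-4`, `sub-chemostat-4.1`,
#' `sub-chemostat-4.2`). They are versioned YAML files shipped with the
#' package.
#'
#' @param name preset name, see \code{\link{list_presets}}.
#' @return List with elements \code{name}, \code{version},
#'   \code{description}, \code{config} (\code{\link{chemostat_config}}),
#'   \code{producer}, \code{nonproducer} (\code{\link{strain_params}}) and
#'   \code{noise} (\code{\link{noise_model}}).
#' @export
load_preset <- function(name) {
  dir <- system.file("extdata", "presets", package = "chemodegen")
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("unknown preset \"", name, "\"; available: ",
         paste(list_presets(), collapse = ", "))
  y <- yaml::read_yaml(path)
  list(name = y$name, version = y$version, description = y$description,
       config = do.call(chemostat_config, y$config),
       producer = do.call(strain_params, y$producer),
       nonproducer = do.call(strain_params, y$nonproducer),
       noise = noise_model(relative_sd = unlist(y$noise$relative_sd),
                           sampling_interval = y$noise$sampling_interval))
}

#' Simulate a scenario preset
#'
#' Convenience wrapper: load a preset and run \code{\link{simulate_culture}}.
#'
#' @inheritParams load_preset
#' @param ... passed on to \code{\link{simulate_culture}}.
#' @return A \code{culture_sim} object.
#' @export
simulate_preset <- function(name = "chemostat-1", ...) {
  p <- load_preset(name)
  simulate_culture(p$config, p$producer, p$nonproducer, ...)
}
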