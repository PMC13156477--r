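#' Bundled simulation scenarios
#'
#' Three reference configurations used throughout calibration and
#' parameter-recovery checks, also shipped as YAML under
#' \code{inst/extdata}:
#' \describe{
#'   \item{null}{all effect sizes zero — every downstream statistic should
#'     sit at its calibrated null distribution.}
#'   \item{conserved_filter}{strong, phylogenetically conserved (Brownian)
#'     size preference during colonization and size-dependent survival:
#'     habitat size acts as a filter whose trait is heritable.}
#'   \item{convergent_defense}{strong predator effects (oviposition
#'     deterrence and consumptive mortality) whose underlying avoidance
#'     and vulnerability traits are white noise, i.e. convergent across
#'     lineages.}
#' }
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [simulationConfig()].
#' @return a [simulationConfig()] list.
#' @export
nullConfig <- function(seed = 1L, ...) simulationConfig(seed = seed, ...)

#' @rdname nullConfig
#' @export
conservedFilterConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, betaSize = 1, gammaSize = 0.5,
               traitModels = list(
                 pref = list(model = "BM", sigma = 1),
                 avoid = list(model = "BM", sigma = 1),
                 tol = list(model = "BM", sigma = 1),
                 vuln = list(model = "BM", sigma = 1)))
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

#' @rdname nullConfig
#' @export
convergentDefenseConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, gammaAvoid = 2, gammaPred = 2,
               traitModels = list(
                 pref = list(model = "BM", sigma = 1),
                 avoid = list(model = "WN", sigma = 1),
                 tol = list(model = "BM", sigma = 1),
                 vuln = list(model = "WN", sigma = 1)))
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

#' Read a simulation scenario from YAML
#'
#' The YAML maps directly onto [simulationConfig()] arguments; nested
#' keys \code{traitModels}, \code{capacityRange} and \code{traitShifts}
#' follow the same structure.
#'
#' @param path YAML file, e.g.
#'   \code{system.file("extdata", "conserved_filter.yaml",
#'   package = "phylopatch")}.
#' @param seed optional seed overriding the file's.
#' @return a [simulationConfig()] list.
#' @export
readScenario <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$traitShifts)) cfg$traitShifts <- unlist(cfg$traitShifts)
  if (!is.null(seed)) cfg$seed <- seed
  do.call(simulationConfig, cfg)
}
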