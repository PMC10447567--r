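# YAML run configuration: a flat `parameters:` block (standard values
# by default), a `dose:` block, and an optional `scenario:` block.
# Unknown keys fail fast so typos cannot silently fall back to defaults.

#' Load a run configuration file
#'
#' Reads a YAML file with up to three blocks:
#' \preformatted{
#' parameters:        # any subset of the model parameters
#'   S_in_G: 100
#'   k_B_D: 10
#' dose:              # any subset of time1, time2, dose1, dose2
#'   dose1: 500
#'   dose2: 500
#' scenario:          # optional
#'   case: B          # A..G
#'   value: 500       # sweep value for cases D/G
#'   t_final: 100
#' }
#' An empty file yields the full standard parameter set and a dosing-off
#' schedule. Unknown keys in any block are an error.
#'
#' @param path path to the YAML file.
#' @return list with validated `params` ([biofilm_params()]), `schedule`
#'   ([dose_schedule()]) and `scenario` (list or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), c("parameters", "dose", "scenario"))
  if (length(bad) > 0)
    stop("unknown top-level config block(s): ", paste(bad, collapse = ", "))
  params <- do.call(biofilm_params, as.list(cfg$parameters))
  dose_args <- as.list(cfg$dose)
  bad <- setdiff(names(dose_args), c("time1", "time2", "dose1", "dose2"))
  if (length(bad) > 0)
    stop("unknown dose key(s): ", paste(bad, collapse = ", "))
  schedule <- do.call(dose_schedule, dose_args)
  scen <- cfg$scenario
  if (!is.null(scen)) {
    bad <- setdiff(names(scen), c("case", "value", "t_final"))
    if (length(bad) > 0)
      stop("unknown scenario key(s): ", paste(bad, collapse = ", "))
  }
  list(params = params, schedule = schedule, scenario = scen)
}

#' Write the effective configuration next to a run's outputs
#'
#' Serializes the full parameter set and schedule actually used, so the
#' run can be reproduced from its own output directory.
#'
#' @param params a [biofilm_params()].
#' @param schedule a [dose_schedule()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, schedule, path) {
  yaml::write_yaml(list(parameters = lapply(unclass(params), identity),
                        dose = unclass(schedule)), path)
  invisible(path)
}
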