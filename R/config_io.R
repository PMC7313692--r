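#' Write / read a scenario configuration as YAML
#'
#' Serializes the scalar fields of a [scenario_config()] so a run can be
#' reproduced from a plain-text config file. (Coupling curves are R
#' functions and are configured in code.)
#'
#' @param cfg a `scenario_config`.
#' @param path YAML file path.
#' @return `write_scenario_yaml`: invisibly, `path`;
#'   `read_scenario_yaml`: a validated `scenario_config`.
#' @export
write_scenario_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(scenario_config, vals)
}
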