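# Run configuration serialization (YAML) and run manifests. A manifest
# embeds the fully resolved configuration plus provenance, so a run is
# re-executable from its manifest alone.

#' Write and read run configurations
#'
#' Serializes a [protocol_config()] to YAML with an explicit unit-system
#' stanza, and reads it back. Configurations round-trip unchanged.
#'
#' @param config A `poremd_config`.
#' @param file Path to the YAML file.
#' @return `write_run_config()` returns `file` invisibly; `read_run_config()`
#'   returns the `poremd_config`.
#' @export
write_run_config <- function(config, file) {
  stopifnot(inherits(config, "poremd_config"))
  payload <- list(
    units = list(system = "lennard-jones",
                 note = "eps = sigma_P = m = k_B = 1; see unit_system() for SI scales"),
    run = unclass(config))
  yaml::write_yaml(payload, file,
                   handlers = list(numeric = function(x) {
                     if (is.infinite(x)) ".inf" else x
                   }))
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  payload <- yaml::read_yaml(file)
  run <- payload$run
  if (is.null(run)) rlang::abort("not a run configuration file: missing `run` stanza")
  run$k <- parse_inf(run$k)
  run$fail_lateral <- parse_inf(run$fail_lateral)
  run$fail_sustain <- parse_inf(run$fail_sustain)
  cfg <- do.call(protocol_config, c(
    run[setdiff(names(run), c("pore_radius"))],
    list(pore = run$pore_radius)))
  cfg
}

parse_inf <- function(x) {
  if (is.character(x) && x %in% c(".inf", "inf", "Inf")) Inf else x
}

#' Write a run manifest
#'
#' Records the resolved configuration together with provenance (package
#' version, R version, timestamp and the outcome tallies when given), so the
#' run can be reproduced exactly.
#'
#' @param config A `poremd_config`.
#' @param file Output YAML path.
#' @param tallies Optional named counts by trajectory status.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(config, file, tallies = NULL) {
  stopifnot(inherits(config, "poremd_config"))
  payload <- list(
    package = list(name = "poremd",
                   version = as.character(utils::packageVersion("poremd")),
                   r_version = R.version.string,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    units = list(system = "lennard-jones"),
    run = unclass(config),
    results = if (!is.null(tallies)) as.list(tallies))
  yaml::write_yaml(payload, file,
                   handlers = list(numeric = function(x) {
                     if (is.infinite(x)) ".inf" else x
                   }))
  invisible(file)
}
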