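#' Read a dataset schema from a YAML configuration file
#'
#' The file maps variable names to specs, e.g.
#' ```yaml
#' os_months: {role: outcome_time}
#' os_event:  {role: outcome_event}
#' age:       {kind: continuous}
#' iss:       {kind: ordinal, levels: [I, II, III]}
#' ldh:       {kind: continuous, transform: log}
#' ```
#' Omitted fields take the [variable_spec()] defaults.
#'
#' @param path YAML file path.
#' @return a `trial_schema`.
#' @export
schema_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_micoxpen("the yaml package is required to read schema files")
  raw <- yaml::read_yaml(path)
  specs <- lapply(names(raw), function(nm) {
    f <- raw[[nm]]
    variable_spec(nm,
                  kind = f$kind %||% "continuous",
                  role = f$role %||% "predictor",
                  transform = f$transform %||% "none",
                  levels = f$levels,
                  standardize = f$standardize)
  })
  schema(specs)
}

#' Write a run manifest
#'
#' JSON stamp written next to every command-line artifact set: package
#' version, root seed, and a fingerprint of the configuration, sufficient to
#' replay the run.
#'
#' @param path output JSON path.
#' @param config the run configuration (any R list).
#' @param seed root seed.
#' @param command label of the command that produced the artifacts.
#' @export
write_manifest <- function(path, config, seed, command = "run") {
  jsonlite::write_json(
    list(package = "micoxpen",
         version = as.character(utils::packageVersion("micoxpen")),
         command = command, seed = seed,
         config_hash = config_hash(config),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE)
  invisible(path)
}
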