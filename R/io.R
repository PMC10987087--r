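#' Write activity metrics as a JSON record
#'
#' Serialises an [activity_metrics()] result together with the parameters
#' that produced it, so every stored metric is reproducible.
#'
#' @param metrics list from [activity_metrics()].
#' @param path output JSON file.
#' @param parameters named list of parameters to record alongside.
#' @return the path, invisibly.
#' @export
write_metrics_json <- function(metrics, path, parameters = list()) {
  jsonlite::write_json(c(metrics, list(parameters = parameters)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a metrics JSON record
#' @param path JSON file written by [write_metrics_json()].
#' @return list of metrics.
#' @export
read_metrics_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a run manifest
#'
#' Every pipeline run records its inputs, parameters (including defaulted
#' ones), seeds, package version and output file hashes in one JSON
#' manifest, so runs can be audited and reproduced exactly.
#'
#' @param path manifest file.
#' @param command subcommand name.
#' @param inputs,outputs character vectors of file paths.
#' @param parameters named list of all effective parameters.
#' @param seed master seed of the run.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, command, inputs = character(0),
                           outputs = character(0), parameters = list(),
                           seed = NA) {
  hash_of <- function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  jsonlite::write_json(
    list(command = command,
         package_version = as.character(utils::packageVersion("adfc")),
         seed = seed,
         inputs = inputs,
         parameters = parameters,
         outputs = lapply(stats::setNames(outputs, outputs), hash_of)),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
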