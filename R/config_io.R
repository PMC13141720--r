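#' Read a QC configuration from a JSON file
#'
#' Key names mirror the [qc_config()] arguments; absent keys keep their
#' defaults.
#'
#' @param path JSON file.
#' @return A `qc_config`.
#' @export
read_qc_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(qc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown qc_config key(s): ", paste(unknown, collapse = ", "))
  do.call(qc_config, vals)
}

#' Read a pipeline configuration from a JSON file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a nested `qc`
#' object is passed through [qc_config()]. Absent keys keep their defaults.
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$qc)) vals$qc <- do.call(qc_config, as.list(vals$qc))
  do.call(pipeline_config, vals)
}
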