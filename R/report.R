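#' Serialize a results bundle to a machine-readable report
#'
#' Writes the structured output of a run (component statistics, GLM
#' summaries, enrichment and drug-screen tables, parameters actually used)
#' as a single JSON document.  Data frames become arrays of row objects;
#' floats are written at full precision so a write/read round trip is the
#' identity on values.
#'
#' @param results_bundle a (possibly nested) named list of scalars, vectors
#'   and data frames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results_bundle, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  results_bundle <- strip_classes(results_bundle)
  json <- jsonlite::toJSON(results_bundle, dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) rlang::abort(sprintf("cannot write report to %s", path))
  invisible(path)
}

# drop bespoke S3 classes (but keep data frames) so jsonlite can serialize
strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, strip_classes))
  x
}

#' Read back a report written by [write_report()]
#'
#' @param path report file.
#' @return nested list; tables come back as tibbles.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rapply(x, how = "replace", classes = "data.frame", tibble::as_tibble)
}
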