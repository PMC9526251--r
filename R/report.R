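#' Quality-control report
#'
#' Container pairing each reported metric with the threshold it was judged
#' against and the resulting pass/fail flag, plus provenance (analysis
#' kind, input file, timestamp, software version). Serializes losslessly
#' to JSON and CSV.
#'
#' @param analysis Analysis kind (e.g. \code{"psf"}, \code{"field"}).
#' @param metrics A data frame with columns \code{metric} (character),
#'   \code{value} (numeric), \code{threshold} (numeric, may be \code{NA}
#'   for purely informational metrics), \code{pass} (logical, \code{NA}
#'   when no threshold applies).
#' @param input Input file or description (character).
#' @param meta Optional \code{\link{acquisition_meta}}; stored as a list.
#' @param timestamp Creation time (POSIXct); defaults to now.
#'
#' @return An object of class \code{qc_report}.
#' @export
qc_report <- function(analysis, metrics, input = NA_character_,
                      meta = NULL, timestamp = Sys.time()) {
  stopifnot(is.data.frame(metrics),
            all(c("metric", "value", "threshold", "pass") %in% names(metrics)))
  structure(
    list(analysis = analysis,
         metrics = metrics[c("metric", "value", "threshold", "pass")],
         input = input,
         meta = if (is.null(meta)) NULL else unclass_deep(meta),
         version = as.character(utils::packageVersion("microqc")),
         timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%S%z")),
    class = "qc_report"
  )
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<QC report: %s (%s)>\n", x$analysis, x$input))
  m <- x$metrics
  status <- ifelse(is.na(m$pass), "  --  ", ifelse(m$pass, "  PASS", "  FAIL"))
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-24s %10.5g  (limit %s)%s\n", m$metric[i], m$value[i],
                ifelse(is.na(m$threshold[i]), "-", format(m$threshold[i])),
                status[i]))
  }
  invisible(x)
}

# Assemble a metrics data frame row by row; helper used by the analyses.
metric_row <- function(metric, value, threshold = NA_real_, pass = NA) {
  data.frame(metric = metric, value = value, threshold = threshold,
             pass = pass, stringsAsFactors = FALSE)
}

#' Write a QC report to JSON
#'
#' @param report A \code{\link{qc_report}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a QC report from JSON
#'
#' Inverse of \code{\link{write_report_json}}; the metrics table and all
#' scalar fields round-trip exactly.
#'
#' @param path Path to a JSON report.
#' @return A \code{qc_report}.
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path)
  metrics <- do.call(rbind, lapply(x$metrics, function(r) {
    data.frame(metric = r$metric,
               value = null_na(r$value),
               threshold = null_na(r$threshold),
               pass = null_na(r$pass, NA),
               stringsAsFactors = FALSE)
  }))
  out <- structure(
    list(analysis = x$analysis, metrics = metrics, input = null_na(x$input),
         meta = x$meta, version = x$version, timestamp = x$timestamp),
    class = "qc_report")
  out
}

null_na <- function(x, na = NA_real_) if (is.null(x)) na else x

#' Write a QC report's metric table to CSV
#'
#' @param report A \code{\link{qc_report}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  m <- report$metrics
  m$analysis <- report$analysis
  m$input <- report$input
  m$timestamp <- report$timestamp
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
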