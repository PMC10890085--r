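# CSV dialect everywhere: UTF-8, comma separator, "." decimal, one header
# row; lines starting with '#' carry provenance and are skipped on read.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}

.provenance_lines <- function(provenance) {
  if (is.null(provenance)) return(character(0))
  paste0("# ", names(provenance), "=", unlist(provenance))
}

.write_csv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- .provenance_lines(provenance)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a peak-area table from CSV
#'
#' Layout: first column `sample_id`, remaining columns one per compound
#' id; empty cells are missing values (kept distinct from literal 0).
#'
#' @param path CSV path.
#' @param samples,compounds Optional metadata data.frames attached to the
#'   result (see [peak_table()]).
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, samples = NULL, compounds = NULL) {
  df <- .read_csv(path)
  if (names(df)[1] != "sample_id") {
    stop("peak table must start with a 'sample_id' column, got '",
         names(df)[1], "'", call. = FALSE)
  }
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cn <- names(df)[-1]
  if (anyDuplicated(cn)) {
    stop("duplicate compound ids: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  peak_table(m, samples = samples, compounds = compounds)
}

#' Write a peak-area table to CSV
#'
#' Missing values are written as empty cells. Round-trips through
#' [read_peak_table()] exactly.
#'
#' @param table A [peak_table()].
#' @param path Output path.
#' @param provenance Optional named list written as `# key=value` comment
#'   lines above the header.
#' @export
write_peak_table <- function(table, path, provenance = NULL) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(sample_id = rownames(table$areas),
                   table$areas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_csv(df, path, provenance)
}

#' Read / write a compound library CSV
#'
#' Columns as documented in [validate_compound_library()].
#'
#' @param path CSV path.
#' @return A validated compound-library data.frame with resolved
#'   `target_mz`.
#' @export
read_compound_library <- function(path) {
  validate_compound_library(.read_csv(path))
}

#' @rdname read_compound_library
#' @param lib Compound-library data.frame.
#' @param provenance Optional named list of provenance comments.
#' @export
write_compound_library <- function(lib, path, provenance = NULL) {
  .write_csv(validate_compound_library(lib), path, provenance)
}

#' Read / write a sample-metadata CSV
#'
#' Columns as documented in [validate_sample_meta()].
#'
#' @param path CSV path.
#' @return A validated sample-metadata data.frame.
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(.read_csv(path))
}

#' @rdname read_sample_meta
#' @param meta Sample-metadata data.frame.
#' @param provenance Optional named list of provenance comments.
#' @export
write_sample_meta <- function(meta, path, provenance = NULL) {
  .write_csv(validate_sample_meta(meta), path, provenance)
}

#' Write / read a QC report as JSON
#'
#' @param report A `qc_report` object from [qc_filter()].
#' @param path JSON path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_qc_report
#' @return `read_qc_report()` returns the report as a `qc_report` list
#'   with a `metrics` data.frame.
#' @export
read_qc_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$metrics <- as.data.frame(x$metrics, stringsAsFactors = FALSE)
  structure(x, class = "qc_report")
}
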