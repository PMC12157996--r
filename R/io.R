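# Delimited-file readers/writers. Comma-separated, "." decimal, UTF-8 is the
# only on-disk format; every file carries a header matching one of the
# documented schemas.

#' Table schemas
#'
#' Column names and types of the delimited tables the pipeline reads and
#' writes:
#' \describe{
#'   \item{design}{`run` (int), `ethanol_pct`, `temp_C`, `time_min`,
#'     `replicate` (int), `response` — factorial experiment observations.}
#'   \item{timecourse}{`ethanol_pct`, `temp_C`, `time_min`, `response` —
#'     extraction time courses.}
#'   \item{rates}{`series_id` (chr), `temp_C`, `k` — rate-constant series.}
#'   \item{doseresponse}{`sample_id` (chr), `concentration_ug_ml`,
#'     `inhibition_pct` — dose-response curves.}
#'   \item{dilution}{`strain` (chr), `concentration_ug_ml`, `inhibited`
#'     (0/1) — microdilution growth flags.}
#'   \item{panel}{`condition_id` (chr), `assay_id` (chr), `ic50_ug_ml` —
#'     long-format activity panel.}
#' }
#'
#' @return Named list of schema definitions (column name -> type).
#' @examples
#' names(extraction_schemas())
#' @export
extraction_schemas <- function() {
  list(
    design = c(run = "integer", ethanol_pct = "numeric", temp_C = "numeric",
               time_min = "numeric", replicate = "integer",
               response = "numeric"),
    timecourse = c(ethanol_pct = "numeric", temp_C = "numeric",
                   time_min = "numeric", response = "numeric"),
    rates = c(series_id = "character", temp_C = "numeric", k = "numeric"),
    doseresponse = c(sample_id = "character", concentration_ug_ml = "numeric",
                     inhibition_pct = "numeric"),
    dilution = c(strain = "character", concentration_ug_ml = "numeric",
                 inhibited = "integer"),
    panel = c(condition_id = "character", assay_id = "character",
              ic50_ug_ml = "numeric"))
}

#' Read and validate a delimited table
#'
#' Reads a CSV file and checks it against one of the documented schemas:
#' the header must contain exactly the schema's columns (missing or
#' duplicated columns are schema errors naming the column) and every cell
#' must parse to the declared type (a non-numeric cell is a parse error
#' reporting the row index). Row order is preserved.
#'
#' @param path path to a CSV file.
#' @param schema schema id, one of `names(extraction_schemas())`.
#' @return A validated data frame with the schema's column order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(series_id = "a", temp_C = c(30, 40), k = c(1, 2)),
#'           f, row.names = FALSE)
#' read_extraction_table(f, "rates")
#' @export
read_extraction_table <- function(path, schema) {
  schemas <- extraction_schemas()
  if (!schema %in% names(schemas))
    stop_ec("unknown schema `%s` (have: %s)", schema,
            paste(names(schemas), collapse = ", "), class = "schema_error")
  if (!file.exists(path))
    stop_ec("file not found: %s", path, class = "io_error")
  spec <- schemas[[schema]]
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  dup <- unique(names(raw)[duplicated(names(raw))])
  if (length(dup))
    stop_ec("duplicated column(s) in %s: %s", path,
            paste(dup, collapse = ", "), class = "schema_error")
  missing <- setdiff(names(spec), names(raw))
  if (length(missing))
    stop_ec("missing column(s) in %s: %s", path,
            paste(missing, collapse = ", "), class = "schema_error")
  extra <- setdiff(names(raw), names(spec))
  if (length(extra))
    stop_ec("unexpected column(s) in %s: %s", path,
            paste(extra, collapse = ", "), class = "schema_error")

  out <- raw[names(spec)]
  for (col in names(spec)) {
    if (spec[[col]] == "character") next
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(parsed) & !is.na(out[[col]]) & out[[col]] != "NA")
    if (length(bad))
      stop_ec("non-numeric value `%s` in column `%s`, row %d of %s",
              out[[col]][bad[1L]], col, bad[1L], path, class = "parse_error")
    out[[col]] <- if (spec[[col]] == "integer") as.integer(round(parsed))
                  else parsed
  }
  out
}

#' Write a delimited table
#'
#' Writes a data frame as CSV under a named schema (header check only, the
#' inverse of [read_extraction_table()]); numeric columns keep full double
#' precision (15 significant digits), so a read round-trip reproduces the
#' table to well within 12 significant digits.
#'
#' @param x data frame matching the schema's columns.
#' @param path output path.
#' @param schema schema id.
#' @return `path`, invisibly.
#' @export
write_extraction_table <- function(x, path, schema) {
  spec <- extraction_schemas()[[schema]]
  if (is.null(spec))
    stop_ec("unknown schema `%s`", schema, class = "schema_error")
  missing <- setdiff(names(spec), names(x))
  if (length(missing))
    stop_ec("missing column(s): %s", paste(missing, collapse = ", "),
            class = "schema_error")
  write.csv(x[names(spec)], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a result report
#'
#' Writes each element of a result bundle as a CSV file (one file per
#' table; objects with an `as.data.frame` method, such as factorial fits
#' and transition-state tables, are coerced first) plus a plain-text run
#' log `run_log.txt` echoing the exact configuration used. Empty tables
#' produce header-only files.
#'
#' @param results named list of data frames or coercible objects.
#' @param path output directory (created if needed).
#' @param config the [run_config()] to echo into the log.
#' @return Character vector of written file paths, invisibly.
#' @examples
#' fit <- fit_factorial(erica_factorial("hep2c"))
#' dir <- tempfile()
#' write_extraction_report(list(coefficients = fit), dir)
#' @export
write_extraction_report <- function(results, path, config = run_config()) {
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results)))
    stop_ec("results must be a named list", class = "value_error")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok) stop_ec("cannot create output directory %s", path,
                   class = "io_error")
  files <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    f <- file.path(path, paste0(nm, ".csv"))
    write.csv(df, f, row.names = FALSE, fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  log_file <- file.path(path, "run_log.txt")
  writeLines(c(
    paste0("phytoextract ",
           as.character(utils::packageVersion("phytoextract"))),
    paste0("tables: ", paste(names(results), collapse = ", ")),
    "config:",
    paste0("  alpha = ", config$alpha),
    paste0("  rate_unit = ", config$rate_unit),
    paste0("  ss_convention = ", config$ss_convention),
    paste0("  seed = ", if (is.null(config$seed)) "<none>" else config$seed),
    paste0("  ic50_scale = ", config$ic50_scale)),
    log_file)
  invisible(c(files, log_file))
}
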