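#' Read a feature x sample expression table
#'
#' Accepts TSV (default) or CSV (by `.csv` extension or `dialect = "csv"`);
#' first column feature ids, header row of sample ids. Duplicate ids,
#' non-numeric cells and ragged rows are rejected with the offending
#' id/position named.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stop_input("file not found: %s", path)
  sep <- switch(dialect,
                auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
                tsv = "\t", csv = ",")
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                      fill = FALSE),
    error = function(e) .stop_input("parse error in %s: %s", path,
                                    conditionMessage(e)))
  if (ncol(dt) < 2) .stop_input("parse error in %s: no sample columns", path)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids))
    .stop_input("duplicate feature id in %s: '%s'", path,
                ids[duplicated(ids)][1L])
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      .stop_input("non-numeric cell in %s, column '%s', data row %d",
                  path, names(vals)[j], bad)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a feature x sample matrix as TSV
#'
#' @param mat Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name of the leading feature-id column.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(mat, path, id_column = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description (ignored), then tab-separated members.
#' Members are de-duplicated preserving order (with a warning); lines with
#' fewer than three fields are a parse error naming the line.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3)
      .stop_input("parse error in %s, line %d: fewer than 3 tab-separated fields",
                  path, i)
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicated member(s) in set '%s' (line %d) de-duplicated",
                      fields[1L], i), call. = FALSE)
      members <- unique(members)
    }
    sets[[fields[1L]]] <- members
  }
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read the clinical table
#'
#' Requires columns `sample_id`, `os_time`, `os_event`; any further columns
#' (age, group, stage, ...) are kept as covariates.
#'
#' @param path TSV/CSV path.
#' @return A data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) .stop_input("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stop_input("clinical table %s lacks column '%s'", path, missing[1L])
  if (any(!is.finite(df$os_time)))
    .stop_input("clinical table has non-finite os_time values")
  df
}

#' Read a sample-role sidecar table
#'
#' Two columns: `sample_id` and `role` (`normal` or `tumour`).
#'
#' @param path TSV path.
#' @return Named character vector of roles.
#' @export
read_sample_roles <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "role") %in% names(df)))
    .stop_input("role table %s needs sample_id and role columns", path)
  bad <- setdiff(unique(df$role), c("normal", "tumour"))
  if (length(bad)) .stop_input("unknown sample role '%s'", bad[1L])
  stats::setNames(df$role, df$sample_id)
}
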