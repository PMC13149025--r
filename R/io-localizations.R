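#' Read a localization table
#'
#' Reads MINFLUX localizations from the canonical CSV/TSV layout
#' (`trace_id,t,x,y,z,efo,valid`) or from an Imspector `.mat` export
#' (fields `loc`/`tid`/`tim`/`efo`/`vld`, coordinates in metres). Rows
#' flagged invalid are dropped (count reported via a message); coordinates
#' are converted to nanometres.
#'
#' @param path file path.
#' @param dialect one of `"csv"`, `"tsv"`, `"imspector-mat"`.
#' @param units unit of the on-disk coordinates for csv/tsv: `"nm"`
#'   (canonical) or `"m"` (converted by 1e9). MAT exports are always metres.
#' @return canonical localization data.frame.
#' @export
read_localizations <- function(path, dialect = c("csv", "tsv", "imspector-mat"),
                               units = c("nm", "m")) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop_mfx("file not found: %s", path)
  table <- switch(dialect,
    csv = read.csv(path),
    tsv = read.delim(path),
    `imspector-mat` = {
      units <- "m"
      mat_to_localizations(read_mat5(path))
    })
  missing <- setdiff(LOC_COLUMNS, names(table))
  if (length(missing))
    stop_mfx("input is missing required column(s): %s",
             paste(missing, collapse = ", "))
  table$valid <- as.logical(table$valid)
  n_invalid <- sum(!table$valid)
  if (n_invalid > 0) {
    message(sprintf("dropping %d invalid-flagged localization(s)", n_invalid))
    table <- table[table$valid, , drop = FALSE]
  }
  if (units == "m") {
    table$x <- table$x * 1e9
    table$y <- table$y * 1e9
    table$z <- table$z * 1e9
  }
  rownames(table) <- NULL
  validate_localizations(table)
}

#' Write a localization table (canonical CSV/TSV)
#'
#' @param table localization data.frame.
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  missing <- setdiff(LOC_COLUMNS, names(table))
  if (length(missing))
    stop_mfx("table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  table <- table[, LOC_COLUMNS, drop = FALSE]
  sep <- if (format == "csv") "," else "\t"
  ok <- tryCatch({
    write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_mfx("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

# Map a parsed Imspector MAT export onto the canonical table. Tolerates both
# a struct with fields (struct-of-arrays) and top-level variables, and takes
# the final targeting iteration when arrays carry one column per iteration.
mat_to_localizations <- function(vars) {
  fields <- c("loc", "tid", "tim", "efo", "vld")
  src <- NULL
  if (all(fields %in% names(vars))) {
    src <- vars
  } else {
    for (v in vars) {
      if (is.list(v) && all(fields %in% names(v))) { src <- v; break }
    }
  }
  if (is.null(src))
    stop_mfx("MAT file does not contain the Imspector fields %s",
             paste(fields, collapse = "/"))
  last_iter <- function(a) {
    if (is.null(dim(a)) || length(dim(a)) == 1) return(as.numeric(a))
    if (length(dim(a)) == 2) {
      # MATLAB stores vectors as 1 x N or N x 1; a genuine N x K matrix
      # carries one column per targeting iteration -> take the last
      if (nrow(a) == 1 || ncol(a) == 1) as.numeric(a) else a[, ncol(a)]
    } else a
  }
  loc <- src$loc
  if (length(dim(loc)) == 3) loc <- loc[, dim(loc)[2], ]  # N x iter x 3
  loc <- as.matrix(loc)
  if (ncol(loc) != 3) stop_mfx("'loc' must have 3 coordinate columns")
  make_loc_table(trace_id = as.integer(last_iter(src$tid)),
                 t = last_iter(src$tim),
                 x = loc[, 1], y = loc[, 2], z = loc[, 3],
                 efo = last_iter(src$efo),
                 valid = last_iter(src$vld) != 0)
}
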