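#' Read and write registry CSV files
#'
#' The registry schema is a flat CSV with one header row and columns
#' `hospital_id, year, procedure, tumour_type, cd_grade_3a_plus, death,
#' readmission, los_days, margin_adequate, popf_bc, reoperation`.
#' Booleans are serialised as `0`/`1`; optional fields that do not apply
#' to a procedure family are empty strings.  Writing then reading a
#' registry preserves every field and type exactly.
#'
#' @param records Registry data frame.
#' @param path File path.
#' @return `read_registry()` returns the registry data frame;
#'   `write_registry()` returns `path` invisibly.
#' @export
write_registry <- function(records, path) {
  missing <- setdiff(REGISTRY_COLUMNS, names(records))
  if (length(missing) > 0)
    stop(sprintf("registry lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- records[, REGISTRY_COLUMNS]
  if (any(grepl("[,\"\n]", out$hospital_id)))
    stop("hospital_id must not contain commas, quotes or newlines",
         call. = FALSE)
  for (col in c("cd_grade_3a_plus", "death", "readmission",
                "margin_adequate", "popf_bc", "reoperation"))
    out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(hospital_id = "character",
                                        tumour_type = "character"))
  missing <- setdiff(REGISTRY_COLUMNS, names(raw))
  if (length(missing) > 0)
    stop(sprintf("registry file lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  raw$year <- as.integer(raw$year)
  raw$los_days <- as.integer(raw$los_days)
  for (col in c("cd_grade_3a_plus", "death", "readmission",
                "margin_adequate", "popf_bc", "reoperation"))
    raw[[col]] <- as.logical(as.integer(raw[[col]]))
  raw[, REGISTRY_COLUMNS]
}

#' Validate a registry against the schema
#'
#' Per-column type and domain checks, per-procedure presence checks of the
#' conditional fields (margin adequacy for liver; POPF and reoperation for
#' pancreas), and duplicate-row detection.  The report lists violations
#' with row and column without mutating the data.
#'
#' @param x Registry data frame or path to a registry CSV.
#' @return Data frame of class `registry_validation` with columns `row`,
#'   `column`, `problem` (zero rows when the registry is valid); attribute
#'   `n_records`.
#' @examples
#' reg <- simulate_registry(audit_sim_config(seed = 2, years = 2021))
#' validate_registry(reg)
#' @export
validate_registry <- function(x) {
  records <- if (is.character(x)) read_registry(x) else x
  v <- list()
  flag <- function(row, column, problem)
    v[[length(v) + 1]] <<- data.frame(row = row, column = column,
                                      problem = problem)
  missing <- setdiff(REGISTRY_COLUMNS, names(records))
  for (m in missing) flag(NA_integer_, m, "missing column")
  extra <- setdiff(names(records), REGISTRY_COLUMNS)
  for (m in extra) flag(NA_integer_, m, "unknown column")
  if (length(missing) == 0) {
    bad <- which(is.na(records$year) | records$year != round(records$year))
    for (i in bad) flag(i, "year", "not an integer year")
    bad <- which(!(records$procedure %in% PROCEDURES))
    for (i in bad) flag(i, "procedure", sprintf(
      "unknown procedure '%s'", records$procedure[bad[1]]))
    liver <- records$procedure %in% LIVER_PROCEDURES
    panc <- records$procedure %in% PANCREAS_PROCEDURES
    bad <- which(!is.na(records$tumour_type) &
                   !(records$tumour_type %in% TUMOUR_TYPES))
    for (i in bad) flag(i, "tumour_type", "unknown tumour type")
    bad <- which(panc & !is.na(records$tumour_type))
    for (i in bad) flag(i, "tumour_type",
                        "must be absent for pancreatic records")
    for (col in c("cd_grade_3a_plus", "death", "readmission")) {
      bad <- which(is.na(records[[col]]))
      for (i in bad) flag(i, col, "missing required boolean")
    }
    bad <- which(is.na(records$los_days) | records$los_days < 0 |
                   records$los_days != round(records$los_days))
    for (i in bad) flag(i, "los_days", "must be a non-negative integer")
    bad <- which(liver & is.na(records$margin_adequate))
    for (i in bad) flag(i, "margin_adequate", "required for liver records")
    bad <- which(panc & !is.na(records$margin_adequate))
    for (i in bad) flag(i, "margin_adequate",
                        "must be absent for pancreatic records")
    for (col in c("popf_bc", "reoperation")) {
      bad <- which(panc & is.na(records[[col]]))
      for (i in bad) flag(i, col, "required for pancreatic records")
      bad <- which(liver & !is.na(records[[col]]))
      for (i in bad) flag(i, col, "must be absent for liver records")
    }
  }
  out <- if (length(v) == 0) {
    data.frame(row = integer(), column = character(), problem = character())
  } else {
    do.call(rbind, v)
  }
  # records carry no patient identifier, so identical rows are legitimate;
  # duplicates are reported as a note, not a violation
  attr(out, "duplicate_rows") <-
    if (length(missing) == 0) which(duplicated(records)) else integer()
  attr(out, "n_records") <- nrow(records)
  class(out) <- c("registry_validation", "data.frame")
  out
}

#' @export
print.registry_validation <- function(x, ...) {
  cat(sprintf("Registry validation: %d record(s), %d violation(s)\n",
              attr(x, "n_records"), nrow(x)))
  if (length(attr(x, "duplicate_rows")) > 0)
    cat(sprintf("  note: %d row(s) coincide with an earlier row\n",
                length(attr(x, "duplicate_rows"))))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 20))
  if (nrow(x) > 20) cat(sprintf("  ... and %d more\n", nrow(x) - 20))
  invisible(x)
}
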