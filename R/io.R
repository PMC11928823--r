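# Readers for delimited instrument exports and machine-readable result
# output. Dialect: '#' comment lines, delimiter auto-detected among
# {',', '\t', ';'}, decimal point '.'. Units are declared per column in the
# column map and converted to SI here, never downstream.

#' Read a column map from a YAML file
#'
#' The column map declares, for each quantity the reader needs, which file
#' column holds it and in what unit, e.g.
#' ```yaml
#' columns:
#'   time:         {col: Time, unit: s}
#'   force:        {col: Load, unit: mN}
#'   displacement: {col: Ext,  unit: mm}
#' ```
#'
#' @param path Path to a YAML file with a top-level `columns` block.
#' @return A named list usable as `column_map` in [read_tensile()] /
#'   [read_force_curve()].
#' @export
read_column_map <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("column map file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cols <- cfg$columns %||% cfg
  if (!is.list(cols) || is.null(names(cols))) {
    stop_format("column map must contain a named 'columns' block")
  }
  lapply(cols, function(x) {
    if (is.character(x)) list(col = x, unit = "") else
      list(col = x$col %||% x$column, unit = x$unit %||% "")
  })
}

# Sniff the delimiter from the first non-comment line.
detect_delim <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format(sprintf("file is empty: %s", path))
  first <- lines[1]
  counts <- vapply(c(",", "\t", ";"), function(d) {
    lengths(regmatches(first, gregexpr(d, first, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0L)) stop_format(sprintf("no recognized delimiter (',', tab, ';') in %s", path))
  c(",", "\t", ";")[which.max(counts)]
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          trim_ws = TRUE, show_col_types = FALSE,
                          progress = FALSE)
  as_tibble(df)
}

# Pull one mapped column out of a parsed table, converted to SI.
mapped_column <- function(df, column_map, quantity, path) {
  spec <- column_map[[quantity]]
  if (is.null(spec)) stop_format(sprintf("column map does not declare '%s'", quantity))
  if (!spec$col %in% names(df)) {
    stop_format(sprintf("missing column '%s' (mapped to %s) in %s", spec$col, quantity, path))
  }
  to_si(as.numeric(df[[spec$col]]), spec$unit)
}

#' Read a tensile test export
#'
#' Parses a delimited text export of time, force and displacement, converts
#' to SI per the declared units, and enforces strictly increasing time.
#'
#' @param path Delimited text file ('#' comments; ',', tab or ';' delimiter).
#' @param column_map Named list (or [read_column_map()] result) declaring
#'   `time`, `force` and `displacement` columns with units.
#' @param geometry A [specimen_geometry()].
#' @param preload Reference preload in newtons (default 0.040).
#' @return A [tensile_record()].
#' @export
read_tensile <- function(path, column_map, geometry, preload = 0.040) {
  df <- read_delimited(path)
  if (nrow(df) < 3L) stop_data(sprintf("need at least 3 rows, got %d: %s", nrow(df), path))
  time <- mapped_column(df, column_map, "time", path)
  force <- mapped_column(df, column_map, "force", path)
  displacement <- mapped_column(df, column_map, "displacement", path)
  bad <- which(diff(time) <= 0)
  if (length(bad) > 0L) {
    stop_data(sprintf("time not strictly increasing at row %d", bad[1] + 1L))
  }
  tensile_record(time, force, displacement, geometry = geometry, preload = preload)
}

#' Read an AFM force or friction curve export
#'
#' @param path Delimited text file.
#' @param column_map Named list declaring exactly two quantities, e.g.
#'   `position` and `force` (or `signal`), each with a unit.
#' @return A tibble with the two mapped columns, in SI units, named after the
#'   declared quantities.
#' @export
read_force_curve <- function(path, column_map) {
  df <- read_delimited(path)
  if (nrow(df) == 0L) stop_data(sprintf("no rows in %s", path))
  qs <- names(column_map)
  if (length(qs) != 2L) stop_format("column map for a force curve must declare exactly 2 quantities")
  out <- lapply(qs, function(q) mapped_column(df, column_map, q, path))
  names(out) <- qs
  as_tibble(out)
}

#' Bundle a result with its provenance
#'
#' @param payload Any summary object (tibble row, [maxwell_fit] object, ...).
#' @param ... Named provenance entries (input file, parameters, seed).
#'   A `seed` entry is mandatory whenever the payload derives from synthetic
#'   data.
#' @return A `result_bundle`.
#' @export
result_bundle <- function(payload, ...) {
  prov <- list(...)
  prov$package_version <- as.character(utils::packageVersion("tissuemech"))
  structure(list(payload = payload, provenance = prov), class = "result_bundle")
}

#' Write a result bundle to structured text
#'
#' Serializes to JSON at full precision; `NaN`/`Inf` are written as explicit
#' tokens so that [read_results()] round-trips every numeric field exactly.
#'
#' @param bundle A [result_bundle()] (or any list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(bundle, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("directory does not exist: %s", dir))
  payload <- serialize_payload(bundle)
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           na = "string", null = "null", pretty = TRUE,
                           always_decimal = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write to %s", path))
  invisible(path)
}

serialize_payload <- function(x) {
  if (inherits(x, "result_bundle")) {
    list(payload = serialize_payload(x$payload), provenance = x$provenance)
  } else if (inherits(x, "maxwell_fit")) {
    unclass_fit <- x
    unclass_fit$model <- as.data.frame(tidy(x))
    unclass(unclass_fit)
  } else if (inherits(x, "maxwell_model")) {
    as.data.frame(tidy(x))
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else if (is.list(x)) {
    lapply(x, serialize_payload)
  } else x
}

#' Read back a results file written by [write_results()]
#'
#' @param path Path written by [write_results()].
#' @return The deserialized list; numeric fields (including `NaN`) equal the
#'   originals to full precision.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
  restore_special(x)
}

# jsonlite writes NaN/Inf as strings under na = "string"; map them back.
restore_special <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, restore_special))
  if (is.data.frame(x)) {
    x[] <- lapply(x, restore_special)
    return(x)
  }
  if (is.character(x)) {
    special <- c("NaN", "NA", "Inf", "-Inf")
    if (all(x %in% special | !is.na(suppressWarnings(as.numeric(x))))) {
      if (any(x %in% special)) return(as.numeric(ifelse(x == "NA", NA, x)))
    }
  }
  x
}
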