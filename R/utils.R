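# Internal helpers shared across the package.

#' @importFrom stats rgamma rnorm runif rpois
#' @importFrom utils head tail
NULL

NA_LITERAL <- "n/a"

#' Shortest round-trip decimal rendering of numbers
#'
#' Renders each finite value with the fewest significant digits that still
#' reproduce the double exactly when re-read, so a write/read cycle of a
#' tabular file is lossless. Integral values are rendered without a decimal
#' point; missing values become `"n/a"`.
#'
#' @param x numeric vector.
#' @return character vector, same length as `x`.
#' @keywords internal
format_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_LITERAL)
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

parse_number <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == NA_LITERAL | s == ""] <- NA_real_
  out
}

is_token <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

is_alnum <- function(x) grepl("^[A-Za-z0-9]+$", x)

#' Write lines to a gzip-compressed file with reproducible bytes
#'
#' Base R's gzip connection leaves the header mtime at zero, so two writes of
#' the same text are byte-identical; relied upon for deterministic output.
#' @noRd
write_tsvgz <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  }
  invisible(path)
}

read_tsvgz_lines <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Canonical sidecar JSON: fixed leading key order, remainder alphabetical,
# 4-space indent, trailing newline.
SIDECAR_KEY_ORDER <- c("SamplingFrequency", "StartTime", "Columns",
                       "PhysioType", "RecordedEye", "SampleCoordinateSystem",
                       "SampleCoordinateUnits", "OnsetSource")

order_sidecar_keys <- function(x) {
  keys <- names(x)
  lead <- intersect(SIDECAR_KEY_ORDER, keys)
  rest <- sort(setdiff(keys, lead))
  x[c(lead, rest)]
}

write_json_sidecar <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  x <- order_sidecar_keys(x)
  txt <- jsonlite::toJSON(x, pretty = 4, auto_unbox = TRUE, digits = NA,
                          null = "null", na = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

read_json_sidecar <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

abort_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
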