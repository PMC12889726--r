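# BIDS filename grammar: entities, suffix, extension.
#
# A BIDS basename is a sequence of key-value "entities" separated by
# underscores, a terminal suffix naming the datatype, and an extension:
#   sub-01_task-visualSearch_recording-eye1_physio.tsv.gz

KNOWN_SUFFIXES <- c("physio", "physioevents", "bold", "events", "eeg", "meg",
                    "beh", "T1w", "T2w", "dwi")

# Longest-match first so ".tsv.gz" wins over ".gz".
KNOWN_EXTENSIONS <- c(".tsv.gz", ".nii.gz", ".json", ".tsv", ".nii")

# Canonical ordering of the entities this package emits; unknown entities are
# kept in input order after the known ones.
ENTITY_ORDER <- c("sub", "ses", "task", "acq", "run", "recording")

#' Construct a BIDS path object
#'
#' Bundles the entity list, suffix and extension of one BIDS basename,
#' together with an optional datatype directory. Entities are reordered into
#' the canonical `sub < ses < task < acq < run < recording` sequence; unknown
#' keys follow in their input order.
#'
#' @param entities named character vector of entity values, e.g.
#'   `c(sub = "01", task = "visualSearch")`. Keys and values must be strictly
#'   alphanumeric and keys unique.
#' @param suffix datatype suffix token, e.g. `"physio"`.
#' @param extension file extension including the leading dot; `".tsv.gz"` is
#'   one atomic token.
#' @param datatype_dir optional modality folder (`"func"`, `"eeg"`, `"meg"`,
#'   `"beh"`) used when planning directory placement.
#' @return an object of class `bids_path`.
#' @seealso [format_bids_name()], [parse_bids_name()]
#' @export
#' @examples
#' bids_path(c(sub = "01", task = "visualSearch", recording = "eye1"),
#'           "physio", ".tsv.gz")
bids_path <- function(entities, suffix, extension, datatype_dir = NULL) {
  keys <- names(entities)
  if (is.null(keys) || any(!nzchar(keys))) {
    abort_named("entities must be a named character vector")
  }
  entities <- vapply(entities, as.character, character(1))
  for (i in seq_along(entities)) {
    if (!is_alnum(keys[i])) {
      abort_named("invalid entity key '%s': only [A-Za-z0-9] allowed", keys[i])
    }
    if (!is_alnum(entities[i])) {
      abort_named("invalid entity value '%s' for key '%s': only [A-Za-z0-9] allowed",
                  entities[i], keys[i])
    }
  }
  if (anyDuplicated(keys)) {
    abort_named("duplicate entity key '%s'", keys[anyDuplicated(keys)])
  }
  if (!("sub" %in% keys)) abort_named("'sub' entity is required")
  if (!is_token(suffix) || !is_alnum(suffix)) {
    abort_named("suffix must be a single alphanumeric token")
  }
  if (!extension %in% KNOWN_EXTENSIONS) {
    abort_named("unknown extension '%s'; known: %s", extension,
                paste(KNOWN_EXTENSIONS, collapse = ", "))
  }
  known <- intersect(ENTITY_ORDER, keys)
  unknown <- setdiff(keys, ENTITY_ORDER)
  entities <- entities[c(known, unknown)]
  structure(list(entities = entities, suffix = suffix, extension = extension,
                 datatype_dir = datatype_dir),
            class = "bids_path")
}

#' @export
print.bids_path <- function(x, ...) {
  cat("<bids_path> ", format_bids_name(x$entities, x$suffix, x$extension),
      "\n", sep = "")
  invisible(x)
}

#' Render a BIDS basename from entities, suffix and extension
#'
#' Joins `key-value` pairs with underscores and appends the suffix and
#' extension: `sub-01_task-visualSearch_recording-eye1_physio.tsv.gz`.
#' Deterministic: the same inputs always produce the same string.
#'
#' @inheritParams bids_path
#' @return the basename as a single string.
#' @export
#' @examples
#' format_bids_name(c(sub = "01", task = "visualSearch", recording = "eye1"),
#'                  "physio", ".tsv.gz")
format_bids_name <- function(entities, suffix, extension) {
  bp <- bids_path(entities, suffix, extension)
  paste0(paste(paste0(names(bp$entities), "-", bp$entities), collapse = "_"),
         "_", bp$suffix, bp$extension)
}

#' Parse a BIDS basename into its components
#'
#' Inverse of [format_bids_name()]. The extension is matched longest-first so
#' `.tsv.gz` is recognized as one token (never bare `.gz`).
#'
#' @param filename a basename with no directory separators.
#' @return a [bids_path()] object.
#' @export
#' @examples
#' parse_bids_name("sub-01_task-visualSearch_recording-eye1_physioevents.json")
parse_bids_name <- function(filename) {
  if (!is_token(filename)) abort_named("filename must be a single string")
  if (grepl("[/\\\\]", filename)) {
    abort_named("'%s' contains directory separators; pass a basename", filename)
  }
  ext <- NULL
  for (e in KNOWN_EXTENSIONS) {
    if (endsWith(filename, e)) { ext <- e; break }
  }
  if (is.null(ext)) {
    abort_named("unknown extension on '%s'; known extensions: %s", filename,
                paste(KNOWN_EXTENSIONS, collapse = ", "))
  }
  stem <- substr(filename, 1L, nchar(filename) - nchar(ext))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2L) {
    abort_named("'%s' has no entity segment before the suffix", filename)
  }
  suffix <- parts[length(parts)]
  ent_parts <- parts[-length(parts)]
  keys <- character(0); vals <- character(0)
  for (p in ent_parts) {
    if (!grepl("-", p, fixed = TRUE)) {
      abort_named("segment '%s' in '%s' is not a key-value pair", p, filename)
    }
    kv <- strsplit(p, "-", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort_named("segment '%s' in '%s' is not a single key-value pair", p, filename)
    }
    keys <- c(keys, kv[1]); vals <- c(vals, kv[2])
  }
  names(vals) <- keys
  bids_path(vals, suffix, ext)
}

# Basename without extension, for deriving sibling files of one pair.
format_bids_stem <- function(entities, suffix) {
  bp <- bids_path(entities, suffix, ".json")
  paste0(paste(paste0(names(bp$entities), "-", bp$entities), collapse = "_"),
         "_", bp$suffix)
}

# Sanitize a free-text task label to a BIDS-safe camelCased token:
# "visual search" -> "visualSearch".
sanitize_task_label <- function(label) {
  words <- strsplit(gsub("[^A-Za-z0-9 ]", " ", label), "[ ]+")[[1]]
  words <- words[nzchar(words)]
  if (!length(words)) abort_named("task label '%s' has no alphanumeric content", label)
  capped <- vapply(words[-1], function(w) {
    paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
  }, character(1))
  paste0(c(words[1], capped), collapse = "")
}
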