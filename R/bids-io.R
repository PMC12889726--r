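# Serialization of recordings and event tables to their on-disk BIDS forms
# (headerless TSVGZ + sidecar JSON), directory placement, and the end-to-end
# ASC -> BIDS conversion.
#
# Conventions (fixed here, shared with the validator):
#   * physio / physioevents TSVGZ files carry NO header row; the sidecar's
#     Columns list is the sole column authority.
#   * the missing-value literal is "n/a".
#   * the physio timestamp column holds device time in seconds, so that
#     physioevents onsets can reference it via OnsetSource = "timestamp".
#   * eye -> recording index: left = eye1, right = eye2, cyclopean = eye3.

EYE_INDEX <- c(left = "eye1", right = "eye2", cyclopean = "eye3")
MODALITY_DIRS <- c(func = "func", eeg = "eeg", meg = "meg", beh = "beh",
                   none = "beh")

#' Describe the acquisition a recording belongs to
#'
#' @param subject subject label (alphanumeric).
#' @param task task label; free text is sanitized to a camelCased token
#'   (`"visual search"` becomes `"visualSearch"`).
#' @param session optional session label.
#' @param main_modality the modality the eye-tracker accompanied: `"func"`,
#'   `"eeg"`, `"meg"`, or `"none"` when eye-tracking is the only modality
#'   (data then go to the behavioral folder `beh/`).
#' @param main_modality_start device-time start of the main acquisition in
#'   seconds, used to derive `StartTime`; `NA` when unknown (then
#'   `StartTime = 0`).
#' @param manufacturer,model optional device identity overrides.
#' @return an `acquisition_context` list.
#' @export
acquisition_context <- function(subject, task, session = NULL,
                                main_modality = "none",
                                main_modality_start = NA_real_,
                                manufacturer = NULL, model = NULL) {
  if (!is_token(subject) || !is_alnum(subject)) {
    abort_named("subject label must be alphanumeric")
  }
  if (!is.null(session) && !is_alnum(session)) {
    abort_named("session label must be alphanumeric")
  }
  if (!main_modality %in% names(MODALITY_DIRS)) {
    abort_named("unknown modality '%s'; supported: %s", main_modality,
                paste(names(MODALITY_DIRS), collapse = ", "))
  }
  structure(list(subject = subject, task = sanitize_task_label(task),
                 session = session, main_modality = main_modality,
                 main_modality_start = main_modality_start,
                 manufacturer = manufacturer, model = model),
            class = "acquisition_context")
}

#' Offset of the first physio sample relative to the main acquisition
#'
#' `StartTime` is defined as seconds from the first sample of the main
#' modality (e.g. the first fMRI volume) to the first physio sample, so it is
#' negative exactly when the eye-tracker started before the main modality.
#'
#' @param first_sample_time device time of the first physio sample, seconds.
#' @param main_start_time device time of the main acquisition start, seconds.
#' @return `first_sample_time - main_start_time`, in seconds.
#' @export
#' @examples
#' compute_start_time(7.5, 10.0)   # tracker started 2.5 s early: -2.5
compute_start_time <- function(first_sample_time, main_start_time) {
  if (!is.finite(first_sample_time) || !is.finite(main_start_time)) {
    abort_named("both times must be finite")
  }
  first_sample_time - main_start_time
}

#' Plan the directory placement of physio files
#'
#' Physio recordings live in the modality folder of the data they accompany
#' (`func/`, `eeg/`, `meg/`); when eye-tracking is the only modality they go
#' to the behavioral folder `beh/`.
#'
#' @param ctx an [acquisition_context()].
#' @return relative path fragment, e.g. `"sub-01/ses-01/func"`.
#' @export
plan_layout <- function(ctx) {
  parts <- paste0("sub-", ctx$subject)
  if (!is.null(ctx$session)) parts <- c(parts, paste0("ses-", ctx$session))
  file.path(paste(parts, collapse = "/"), MODALITY_DIRS[[ctx$main_modality]])
}

context_entities <- function(ctx, recording = NULL) {
  ents <- c(sub = ctx$subject)
  if (!is.null(ctx$session)) ents <- c(ents, ses = ctx$session)
  ents <- c(ents, task = ctx$task)
  if (!is.null(recording)) ents <- c(ents, recording = recording)
  ents
}

#' Build the sidecar metadata for a gaze recording
#'
#' Fills the mandatory continuous-recording fields (`SamplingFrequency`,
#' `StartTime`, `Columns`), sets `PhysioType` to the reserved keyword
#' `"eyetrack"` (which makes `RecordedEye` and `SampleCoordinateSystem`
#' mandatory), and emits descriptor objects for every column beyond the
#' mandatory trio.
#'
#' @param rec a [gaze_recording()].
#' @param ctx an [acquisition_context()].
#' @return a [physio_sidecar()].
#' @export
build_physio_sidecar <- function(rec, ctx) {
  start_time <- if (is.finite(ctx$main_modality_start)) {
    compute_start_time(rec$data$timestamp[1], ctx$main_modality_start)
  } else {
    rec$start_time
  }
  col_names <- names(rec$data)
  meta_cols <- setdiff(col_names, MANDATORY_PHYSIO_COLUMNS)
  col_meta <- list()
  for (d in rec$columns) {
    if (d$name %in% meta_cols) col_meta[[d$name]] <- d
  }
  cs <- rec$coordinate_system
  physio_sidecar(
    sampling_frequency = rec$sampling_frequency,
    start_time = start_time,
    columns = col_names,
    physio_type = "eyetrack",
    recorded_eye = rec$recorded_eye,
    sample_coordinate_system = cs$name,
    sample_coordinate_units = cs$units,
    manufacturer = ctx$manufacturer %||% rec$manufacturer,
    model = ctx$model %||% rec$model,
    column_metadata = col_meta,
    extra = list(SampleCoordinateSystemDescription =
                   paste0("origin at ", cs$origin, "; ", cs$description)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_to_list <- function(sc) {
  out <- list(SamplingFrequency = sc$SamplingFrequency,
              StartTime = sc$StartTime, Columns = as.list(sc$Columns))
  for (f in c("PhysioType", "RecordedEye", "SampleCoordinateSystem",
              "SampleCoordinateUnits", "Manufacturer",
              "ManufacturersModelName")) {
    if (!is.null(sc[[f]])) out[[f]] <- sc[[f]]
  }
  for (nm in names(sc$column_metadata)) {
    out[[nm]] <- descriptor_to_json(sc$column_metadata[[nm]])
  }
  c(out, sc$extra)
}

#' Write a physio TSVGZ + sidecar JSON pair
#'
#' The TSVGZ is tab-separated with no header row (the sidecar's `Columns`
#' entry is the column authority), missing cells rendered `"n/a"`, numbers in
#' shortest round-trip decimal form. Output is byte-reproducible: the gzip
#' header carries no timestamp and the JSON uses a canonical key order.
#'
#' @param rec a [gaze_recording()].
#' @param sidecar the matching [physio_sidecar()].
#' @param path a [bids_path()] with suffix `"physio"`.
#' @param root dataset root directory.
#' @param overwrite overwrite existing files? Default `FALSE`.
#' @return invisibly, the two file paths written (tsv.gz, json).
#' @export
write_physio_pair <- function(rec, sidecar, path, root, overwrite = FALSE) {
  if (path$suffix != "physio") abort_named("path suffix must be 'physio'")
  stopifnot(identical(names(rec$data), sidecar$Columns))
  dir <- file.path(root, path$datatype_dir %||% "")
  base <- format_bids_stem(path$entities, "physio")
  tsv <- file.path(dir, paste0(base, ".tsv.gz"))
  json <- file.path(dir, paste0(base, ".json"))
  if (!overwrite && (file.exists(tsv) || file.exists(json))) {
    abort_named("output exists (use overwrite = TRUE): %s", tsv)
  }
  lines <- render_table_rows(rec$data)
  write_tsvgz(lines, tsv)
  write_json_sidecar(sidecar_to_list(sidecar), json)
  invisible(c(tsv, json))
}

render_table_rows <- function(df) {
  if (!nrow(df)) return(character(0))
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) format_number(col)
    else ifelse(is.na(col), NA_LITERAL, as.character(col))
  })
  do.call(paste, c(cols, sep = "\t"))
}

events_sidecar_to_list <- function(sc, col_names) {
  out <- list(Columns = as.list(col_names), OnsetSource = sc$OnsetSource)
  for (nm in names(sc$column_metadata)) {
    if (nm %in% col_names) out[[nm]] <- descriptor_to_json(sc$column_metadata[[nm]])
  }
  c(out, sc$extra)
}

#' Write a physioevents TSVGZ + sidecar JSON pair
#'
#' Column order is fixed: `onset`, `duration`, `event_type`, `eye`,
#' `message`, then the parameter columns in sorted order. Same headerless
#' TSVGZ and canonical-JSON conventions as [write_physio_pair()].
#'
#' @param table an [event_table()].
#' @param sidecar an [events_sidecar()]; its `OnsetSource` must name a column
#'   of the companion physio recording.
#' @inheritParams write_physio_pair
#' @return invisibly, the two file paths written.
#' @export
write_physioevents_pair <- function(table, sidecar, path, root,
                                    overwrite = FALSE) {
  if (path$suffix != "physioevents") {
    abort_named("path suffix must be 'physioevents'")
  }
  param_cols <- sort(setdiff(names(table), EVENT_CORE_COLUMNS))
  described <- names(attr(table, "column_meta")) %||% character(0)
  undeclared <- setdiff(param_cols, described)
  if (length(undeclared)) {
    abort_named("event parameter column(s) not described in the sidecar: %s",
                paste(undeclared, collapse = ", "))
  }
  col_order <- c(EVENT_CORE_COLUMNS, param_cols)
  df <- as.data.frame(table)[col_order]
  dir <- file.path(root, path$datatype_dir %||% "")
  base <- format_bids_stem(path$entities, "physioevents")
  tsv <- file.path(dir, paste0(base, ".tsv.gz"))
  json <- file.path(dir, paste0(base, ".json"))
  if (!overwrite && (file.exists(tsv) || file.exists(json))) {
    abort_named("output exists (use overwrite = TRUE): %s", tsv)
  }
  write_tsvgz(render_table_rows(df), tsv)
  meta <- attr(table, "column_meta")
  sc <- sidecar
  sc$column_metadata <- meta[intersect(col_order, names(meta))]
  write_json_sidecar(events_sidecar_to_list(sc, col_order), json)
  invisible(c(tsv, json))
}

split_tsv_lines <- function(lines) {
  lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
}

#' Read a physio pair back into a gaze recording
#'
#' Exact inverse of [write_physio_pair()] on its image: numeric text is
#' shortest-round-trip so values survive unchanged, and `"n/a"` cells become
#' missing values.
#'
#' @param tsv_path,json_path the two file paths.
#' @return a [gaze_recording()].
#' @export
read_physio_pair <- function(tsv_path, json_path) {
  sc <- read_json_sidecar(json_path)
  cols <- unlist(sc$Columns)
  rows <- split_tsv_lines(read_tsvgz_lines(tsv_path))
  widths <- lengths(rows)
  if (length(widths) && any(widths != length(cols))) {
    bad <- which(widths != length(cols))[1]
    abort_named("ET06: row %d has %d fields but sidecar Columns lists %d",
                bad, widths[bad], length(cols))
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(0), ncol = length(cols))
  data <- as.data.frame(lapply(seq_along(cols), function(i) {
    parse_number(mat[, i])
  }))
  names(data) <- cols
  descs <- lapply(cols, function(nm) {
    obj <- sc[[nm]]
    if (is.list(obj)) {
      column_descriptor(nm, description = obj$Description, units = obj$Units,
                        extra = obj[setdiff(names(obj), c("Description", "Units"))])
    } else column_descriptor(nm)
  })
  gaze_recording(data, descs,
                 sampling_frequency = sc$SamplingFrequency,
                 start_time = sc$StartTime,
                 recorded_eye = sc$RecordedEye %||% "left",
                 coordinate_system = list(
                   name = sc$SampleCoordinateSystem %||% "unknown",
                   units = sc$SampleCoordinateUnits %||% "unknown",
                   origin = "unknown", description = ""),
                 manufacturer = sc$Manufacturer,
                 model = sc$ManufacturersModelName)
}

#' Read a physioevents pair back
#'
#' @inheritParams read_physio_pair
#' @return a list with elements `table` (an [event_table()]) and `sidecar`
#'   (an [events_sidecar()]).
#' @export
read_physioevents_pair <- function(tsv_path, json_path) {
  sc <- read_json_sidecar(json_path)
  cols <- unlist(sc$Columns)
  rows <- split_tsv_lines(read_tsvgz_lines(tsv_path))
  widths <- lengths(rows)
  if (length(widths) && any(widths != length(cols))) {
    bad <- which(widths != length(cols))[1]
    abort_named("ET06: row %d has %d fields but sidecar Columns lists %d",
                bad, widths[bad], length(cols))
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(0), ncol = length(cols))
  df <- as.data.frame(lapply(seq_along(cols), function(i) {
    v <- mat[, i]
    if (cols[i] %in% c("event_type", "eye", "message")) {
      ifelse(v == NA_LITERAL, NA_character_, v)
    } else parse_number(v)
  }), stringsAsFactors = FALSE)
  names(df) <- cols
  meta <- lapply(cols, function(nm) {
    obj <- sc[[nm]]
    if (is.list(obj)) column_descriptor(nm, description = obj$Description,
                                        units = obj$Units)
    else column_descriptor(nm)
  })
  names(meta) <- cols
  list(table = event_table(df, columns = meta),
       sidecar = events_sidecar(sc$OnsetSource %||% "timestamp",
                                column_metadata = meta))
}

write_dataset_description <- function(root, name = "Eye-tracking dataset") {
  path <- file.path(root, "dataset_description.json")
  if (!file.exists(path)) {
    write_json_sidecar(list(Name = name, BIDSVersion = "1.11.0"), path)
  }
  invisible(path)
}

#' Convert a parsed (or on-disk) ASC session into BIDS files
#'
#' For each recorded eye (left first as `recording-eye1`, right as
#' `recording-eye2`) a physio pair and a physioevents pair are written under
#' the modality folder chosen by [plan_layout()]. Monocular sessions still
#' carry the recording entity, which is mandatory under
#' `PhysioType = "eyetrack"`. A minimal `dataset_description.json` stub is
#' created when the root is new. The resulting tree validates cleanly (see
#' [validate_dataset()]).
#'
#' @param asc an `asc_session` from [parse_asc()], or a file path.
#' @param ctx an [acquisition_context()].
#' @param root dataset root directory (created if needed).
#' @param overwrite overwrite existing output files?
#' @return invisibly, the character vector of files written (tsv.gz and json
#'   for each eye's physio and physioevents; 8 files for a binocular
#'   session, 4 for monocular).
#' @export
convert_session <- function(asc, ctx, root, overwrite = FALSE) {
  session <- if (inherits(asc, "asc_session")) asc else read_asc(asc)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  write_dataset_description(root)
  rel_dir <- plan_layout(ctx)
  written <- character(0)
  eyes <- intersect(c("left", "right"), session$eyes)
  for (eye in eyes) {
    rec <- extract_recording(session, eye)
    rec$manufacturer <- ctx$manufacturer %||% rec$manufacturer
    rec$model <- ctx$model %||% rec$model
    sidecar <- build_physio_sidecar(rec, ctx)
    ents <- context_entities(ctx, recording = EYE_INDEX[[eye]])
    p_path <- bids_path(ents, "physio", ".tsv.gz", datatype_dir = rel_dir)
    written <- c(written,
                 write_physio_pair(rec, sidecar, p_path, root, overwrite))
    events <- extract_events(session, eye)
    e_sc <- events_sidecar("timestamp",
                           column_metadata = event_param_descriptors())
    e_path <- bids_path(ents, "physioevents", ".tsv.gz", datatype_dir = rel_dir)
    written <- c(written,
                 write_physioevents_pair(events, e_sc, e_path, root, overwrite))
  }
  invisible(written)
}
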