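# Shared domain types: column descriptors, gaze recordings, sidecars, event
# tables. All are plain lists / data.frames with S3 classes and validating
# constructors.

#' Describe one tabular column
#'
#' @param name column name (non-empty token).
#' @param description optional free-text description.
#' @param units optional unit string (e.g. `"pixels"`, `"arbitrary"`).
#' @param extra named list of additional descriptor fields.
#' @return a `column_descriptor` list.
#' @export
column_descriptor <- function(name, description = NULL, units = NULL,
                              extra = list()) {
  if (!is_token(name)) abort_named("column name must be a non-empty string")
  structure(list(name = name, description = description, units = units,
                 extra = extra),
            class = "column_descriptor")
}

descriptor_to_json <- function(d) {
  out <- list()
  if (!is.null(d$description)) out$Description <- d$description
  if (!is.null(d$units)) out$Units <- d$units
  c(out, d$extra)
}

MANDATORY_PHYSIO_COLUMNS <- c("timestamp", "x_coordinate", "y_coordinate")
RECORDED_EYE_VALUES <- c("left", "right", "cyclopean")

#' Default screen coordinate-system descriptor
#'
#' Gaze-on-screen pixel coordinates with the origin at the top-left corner,
#' x increasing rightward and y increasing downward -- the convention of
#' screen-based video trackers.
#' @param units coordinate units.
#' @return a named list describing the coordinate frame.
#' @export
screen_coordinate_system <- function(units = "pixels") {
  list(name = "gaze-on-screen", units = units,
       origin = "top-left corner of the screen",
       description = "x increases rightward, y increases downward")
}

#' Construct a uniformly sampled gaze recording for one eye
#'
#' Holds the sample table of a single eye (or the cyclopean average stream),
#' its ordered column descriptors, the sampling frequency and the acquisition
#' start offset. Enforced invariants: `timestamp` is the first column,
#' `x_coordinate` and `y_coordinate` are present, exactly one eye per
#' recording, timestamps strictly increasing.
#'
#' @param data data.frame of numeric columns; missing samples are `NA`, never
#'   dropped rows (dropping would break uniform sampling).
#' @param columns list of [column_descriptor()]s in table order; defaults to
#'   bare descriptors built from `names(data)`.
#' @param sampling_frequency sampling rate in Hz (> 0).
#' @param start_time offset in seconds of the first sample relative to the
#'   main acquisition start; negative when the tracker started earlier.
#' @param recorded_eye `"left"`, `"right"` or `"cyclopean"`.
#' @param coordinate_system coordinate-frame descriptor; see
#'   [screen_coordinate_system()].
#' @param manufacturer,model optional device identity strings.
#' @return a `gaze_recording` object.
#' @export
gaze_recording <- function(data, columns = NULL, sampling_frequency,
                           start_time = 0, recorded_eye,
                           coordinate_system = screen_coordinate_system(),
                           manufacturer = NULL, model = NULL) {
  if (!is.data.frame(data)) abort_named("data must be a data.frame")
  if (is.null(columns)) {
    columns <- lapply(names(data), column_descriptor)
  }
  col_names <- vapply(columns, `[[`, character(1), "name")
  if (!identical(col_names, names(data))) {
    abort_named("column descriptors (%s) do not match table columns (%s)",
                paste(col_names, collapse = ","),
                paste(names(data), collapse = ","))
  }
  if (anyDuplicated(col_names)) abort_named("duplicate column names")
  if (length(col_names) < 1L || col_names[1] != "timestamp") {
    abort_named("'timestamp' must be the first column")
  }
  missing_core <- setdiff(MANDATORY_PHYSIO_COLUMNS, col_names)
  if (length(missing_core)) {
    abort_named("missing mandatory column(s): %s",
                paste(missing_core, collapse = ", "))
  }
  if (!is.numeric(sampling_frequency) || sampling_frequency <= 0) {
    abort_named("sampling_frequency must be > 0")
  }
  if (!is.finite(start_time)) abort_named("start_time must be finite")
  if (!recorded_eye %in% RECORDED_EYE_VALUES) {
    abort_named("recorded_eye must be one of %s",
                paste(RECORDED_EYE_VALUES, collapse = ", "))
  }
  ts <- data$timestamp
  if (nrow(data) > 1L && any(diff(ts) <= 0)) {
    abort_named("timestamp column must be strictly increasing")
  }
  structure(list(data = data, columns = columns,
                 sampling_frequency = sampling_frequency,
                 start_time = start_time, recorded_eye = recorded_eye,
                 coordinate_system = coordinate_system,
                 manufacturer = manufacturer, model = model),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s eye, %d samples @ %g Hz, columns: %s\n",
              x$recorded_eye, nrow(x$data), x$sampling_frequency,
              paste(names(x$data), collapse = ", ")))
  invisible(x)
}

EVENT_TYPES <- c("message", "fixation", "saccade", "blink", "start", "stop",
                 "calibration", "trigger", "other")
EVENT_CORE_COLUMNS <- c("onset", "duration", "event_type", "eye", "message")

#' Construct a table of asynchronous device events
#'
#' Events (device messages, fixations, saccades, blinks, recording start/stop
#' marks) are single rows referencing the timescale of a recording column
#' (see `OnsetSource` in [events_sidecar()]). Rows are sorted stably by onset.
#'
#' @param events data.frame with columns `onset` (numeric, required),
#'   `duration` (seconds, `NA` allowed), `event_type` (one of message,
#'   fixation, saccade, blink, start, stop, calibration, trigger, other),
#'   `eye` (`left`/`right`/`cyclopean`/`n/a`), `message` (text, `NA` allowed),
#'   plus any numeric parameter columns (amplitude, peak velocity, ...).
#' @param columns optional list of [column_descriptor()]s for the parameter
#'   columns.
#' @return an `event_table` data.frame (classed).
#' @export
event_table <- function(events = NULL, columns = NULL) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         event_type = character(0), eye = character(0),
                         message = character(0), stringsAsFactors = FALSE)
  }
  missing_core <- setdiff(EVENT_CORE_COLUMNS, names(events))
  for (m in missing_core) events[[m]] <- if (m %in% c("onset", "duration")) NA_real_ else NA_character_
  if (anyNA(events$onset)) abort_named("every event must have an onset")
  bad_dur <- !is.na(events$duration) & events$duration < 0
  if (any(bad_dur)) abort_named("negative duration at row %d", which(bad_dur)[1])
  bad_type <- !events$event_type %in% EVENT_TYPES
  if (any(bad_type)) {
    abort_named("unknown event_type '%s'", events$event_type[bad_type][1])
  }
  extra <- setdiff(names(events), EVENT_CORE_COLUMNS)
  events <- events[c(EVENT_CORE_COLUMNS, extra)]
  events <- events[order(events$onset), , drop = FALSE]  # stable sort
  rownames(events) <- NULL
  structure(events, class = c("event_table", "data.frame"),
            column_meta = columns)
}

#' Sidecar metadata for a physioevents table
#'
#' @param onset_source name of the recording column whose timescale the event
#'   onsets reference (usually `"timestamp"`).
#' @param column_metadata named list of [column_descriptor()]s.
#' @param extra additional sidecar fields.
#' @return an `events_sidecar` list.
#' @export
events_sidecar <- function(onset_source = "timestamp",
                           column_metadata = list(), extra = list()) {
  if (!is_token(onset_source)) abort_named("OnsetSource must be non-empty")
  structure(list(OnsetSource = onset_source,
                 column_metadata = column_metadata, extra = extra),
            class = "events_sidecar")
}

#' Sidecar metadata for a physio recording
#'
#' Validating container for the metadata the standard attaches to continuous
#' physiological recordings, plus the eye-tracking specific fields unlocked
#' when `PhysioType` is the reserved keyword `"eyetrack"` (then `RecordedEye`
#' and `SampleCoordinateSystem` become mandatory).
#'
#' @param sampling_frequency Hz, > 0.
#' @param start_time seconds relative to the main acquisition start; may be
#'   negative (tracker started first).
#' @param columns ordered character vector of table column names.
#' @param physio_type optional recording type token; `"eyetrack"` triggers the
#'   eye-tracking rules.
#' @param recorded_eye,sample_coordinate_system,sample_coordinate_units
#'   eye-tracking fields; see [gaze_recording()].
#' @param manufacturer,model optional device identity.
#' @param column_metadata named list of [column_descriptor()]s; every name
#'   must appear in `columns`.
#' @param extra open named list for further metadata.
#' @return a `physio_sidecar` list.
#' @export
physio_sidecar <- function(sampling_frequency, start_time, columns,
                           physio_type = NULL, recorded_eye = NULL,
                           sample_coordinate_system = NULL,
                           sample_coordinate_units = NULL,
                           manufacturer = NULL, model = NULL,
                           column_metadata = list(), extra = list()) {
  if (!is.numeric(sampling_frequency) || sampling_frequency <= 0) {
    abort_named("SamplingFrequency must be > 0")
  }
  if (!is.finite(start_time)) abort_named("StartTime must be finite")
  if (!length(columns)) abort_named("Columns must be non-empty")
  if (anyDuplicated(columns)) abort_named("Columns names must be unique")
  if (identical(physio_type, "eyetrack")) {
    if (is.null(recorded_eye) || !recorded_eye %in% RECORDED_EYE_VALUES) {
      abort_named("PhysioType 'eyetrack' requires RecordedEye in {%s}",
                  paste(RECORDED_EYE_VALUES, collapse = ", "))
    }
    if (is.null(sample_coordinate_system)) {
      abort_named("PhysioType 'eyetrack' requires SampleCoordinateSystem")
    }
  }
  stray <- setdiff(names(column_metadata), columns)
  if (length(stray)) {
    abort_named("column_metadata for unknown column(s): %s",
                paste(stray, collapse = ", "))
  }
  structure(list(SamplingFrequency = sampling_frequency,
                 StartTime = start_time, Columns = as.character(columns),
                 PhysioType = physio_type, RecordedEye = recorded_eye,
                 SampleCoordinateSystem = sample_coordinate_system,
                 SampleCoordinateUnits = sample_coordinate_units,
                 Manufacturer = manufacturer,
                 ManufacturersModelName = model,
                 column_metadata = column_metadata, extra = extra),
            class = "physio_sidecar")
}
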