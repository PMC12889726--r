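# Parser for the EyeLink ASC plain-text export dialect.
#
# Line grammar handled here (the de-facto ASC export):
#   sample (monocular):  <ts> <x> <y> [<pupil>] [flags]
#   sample (binocular):  <ts> <xL> <yL> <pL> <xR> <yR> <pR> [flags]
#     fields tab/space separated; the missing-value marker is "." and becomes
#     a missing cell; trailing non-numeric flag tokens are ignored.
#   MSG <ts> <free text>
#   EFIX  <L|R> <start> <end> <dur> <x> <y> <pupil>
#   ESACC <L|R> <start> <end> <dur> <x0> <y0> <x1> <y1> <amp> <pv>
#   EBLINK <L|R> <start> <end> <dur>
#   SFIX/SSACC/SBLINK start lines are ignored (their E-counterparts carry the
#   complete information).
#   control: START / END / SAMPLES / EVENTS / PRESCALER / PUPIL /
#            DISPLAY_COORDS; comments: "**" prefix or blank lines.
# Unknown lines are counted, never fatal: strictness lives in the validator.

NUM_OR_MISSING <- "^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$"

is_numeric_field <- function(tok) tok == "." | grepl(NUM_OR_MISSING, tok)

field_value <- function(tok) ifelse(tok == ".", NA_real_,
                                    suppressWarnings(as.numeric(tok)))

split_fields <- function(line) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse an EyeLink ASC session
#'
#' Classifies every line of an ASC export as sample, message, event, control
#' or comment and assembles the parsed session: per-eye sample streams,
#' device messages, fixation/saccade/blink events, sampling rate and screen
#' geometry. Unknown lines are tolerated and counted (`n_unknown`), never
#' fatal.
#'
#' @param lines character vector of ASC text lines (see [read_asc()] to read
#'   from a file, including gzip-compressed ones).
#' @return an `asc_session` list with elements `samples_left`,
#'   `samples_right` (data.frames `time_ms, x, y, pupil`), `messages`,
#'   `events`, `sampling_frequency`, `eyes`, `has_pupil`, `pupil_measure`,
#'   `screen_resolution`, `start_timestamp`, `end_timestamp`, `n_unknown`.
#' @export
parse_asc <- function(lines) {
  rate <- NA_real_
  eyes_declared <- character(0)
  pupil_measure <- NA_character_
  screen <- NULL
  start_ts <- NA_real_; end_ts <- NA_real_
  n_classified <- 0L; n_unknown <- 0L
  sample_lines <- character(0); sample_linenos <- integer(0)
  msg_time <- numeric(0); msg_text <- character(0)
  ev <- list()

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "**")) {
      n_classified <- n_classified + 1L
      next
    }
    toks <- split_fields(line)
    head_tok <- toks[1]
    if (grepl("^[0-9]", head_tok) && is_numeric_field(head_tok)) {
      sample_lines <- c(sample_lines, line)
      sample_linenos <- c(sample_linenos, i)
      n_classified <- n_classified + 1L
      next
    }
    switch(head_tok,
      "MSG" = {
        ts <- field_value(toks[2])
        text <- sub("^[ \t]*MSG[ \t]+[0-9.]+[ \t]?", "", line)
        msg_time <- c(msg_time, ts); msg_text <- c(msg_text, text)
        if (grepl("DISPLAY_COORDS", text)) {
          screen <- parse_display_coords(split_fields(text))
        }
        n_classified <- n_classified + 1L
      },
      "EFIX" = , "ESACC" = , "EBLINK" = {
        ev[[length(ev) + 1L]] <- parse_event_line(head_tok, toks, i)
        n_classified <- n_classified + 1L
      },
      "SFIX" = , "SSACC" = , "SBLINK" = {
        n_classified <- n_classified + 1L   # redundant with E-lines
      },
      "START" = {
        start_ts <- field_value(toks[2]); n_classified <- n_classified + 1L
      },
      "END" = {
        end_ts <- field_value(toks[2]); n_classified <- n_classified + 1L
      },
      "SAMPLES" = {
        if ("LEFT" %in% toks) eyes_declared <- union(eyes_declared, "left")
        if ("RIGHT" %in% toks) eyes_declared <- union(eyes_declared, "right")
        ri <- match("RATE", toks)
        if (!is.na(ri) && length(toks) > ri) rate <- field_value(toks[ri + 1L])
        n_classified <- n_classified + 1L
      },
      "EVENTS" = , "PRESCALER" = , "VPRESCALER" = , "INPUT" = {
        n_classified <- n_classified + 1L
      },
      "PUPIL" = {
        pupil_measure <- tolower(toks[2]); n_classified <- n_classified + 1L
      },
      "DISPLAY_COORDS" = {
        screen <- parse_display_coords(toks); n_classified <- n_classified + 1L
      },
      { n_unknown <- n_unknown + 1L }
    )
  }

  if (n_classified == 0L) {
    abort_named("not an ASC file: zero classifiable lines out of %d",
                length(lines))
  }

  parsed <- parse_sample_block(sample_lines, sample_linenos, eyes_declared)
  eyes <- parsed$eyes
  events <- if (length(ev)) do.call(rbind, ev) else empty_asc_events()

  if (is.na(rate) && nrow(parsed$left) + nrow(parsed$right) > 1L) {
    tbl <- if (nrow(parsed$left)) parsed$left else parsed$right
    dt <- diff(tbl$time_ms)
    mode_dt <- as.numeric(names(sort(table(dt), decreasing = TRUE))[1])
    rate <- round(1000 / mode_dt)
    warning(sprintf("SAMPLES header lacked a RATE field; inferred %g Hz from sample spacing",
                    rate), call. = FALSE)
  }

  all_ts <- c(parsed$left$time_ms, parsed$right$time_ms)
  structure(list(
    samples_left = parsed$left, samples_right = parsed$right,
    messages = data.frame(time_ms = msg_time, text = msg_text,
                          stringsAsFactors = FALSE),
    events = events,
    sampling_frequency = rate, eyes = eyes, has_pupil = parsed$has_pupil,
    pupil_measure = pupil_measure, screen_resolution = screen,
    start_timestamp = if (is.na(start_ts) && length(all_ts)) min(all_ts) else start_ts,
    end_timestamp = if (is.na(end_ts) && length(all_ts)) max(all_ts) else end_ts,
    n_unknown = n_unknown), class = "asc_session")
}

empty_asc_events <- function() {
  data.frame(type = character(0), eye = character(0), start_ms = numeric(0),
             end_ms = numeric(0), duration_ms = numeric(0), x0 = numeric(0),
             y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
             pupil = numeric(0), amplitude = numeric(0),
             peak_velocity = numeric(0), stringsAsFactors = FALSE)
}

parse_event_line <- function(kind, toks, lineno) {
  eye <- c(L = "left", R = "right")[toks[2]]
  if (is.na(eye)) abort_named("line %d: %s with unknown eye tag '%s'",
                              lineno, kind, toks[2])
  v <- field_value(toks[-(1:2)])
  g <- function(i) if (length(v) >= i) v[i] else NA_real_
  data.frame(
    type = switch(kind, EFIX = "fixation", ESACC = "saccade", EBLINK = "blink"),
    eye = eye, start_ms = g(1), end_ms = g(2), duration_ms = g(3),
    x0 = if (kind %in% c("EFIX", "ESACC")) g(4) else NA_real_,
    y0 = if (kind %in% c("EFIX", "ESACC")) g(5) else NA_real_,
    x1 = if (kind == "ESACC") g(6) else NA_real_,
    y1 = if (kind == "ESACC") g(7) else NA_real_,
    pupil = if (kind == "EFIX") g(6) else NA_real_,
    amplitude = if (kind == "ESACC") g(8) else NA_real_,
    peak_velocity = if (kind == "ESACC") g(9) else NA_real_,
    stringsAsFactors = FALSE)
}

parse_display_coords <- function(toks) {
  nums <- suppressWarnings(as.numeric(toks))
  nums <- nums[!is.na(nums)]
  if (length(nums) >= 4L) {
    c(width = nums[3] - nums[1] + 1, height = nums[4] - nums[2] + 1)
  } else NULL
}

# Sample block: field count must be consistent; layout decided by the declared
# eyes (SAMPLES header) or, absent a header, by the field count alone
# (3/4 fields = monocular, 6/7 = binocular).
parse_sample_block <- function(sample_lines, linenos, eyes_declared) {
  empty <- data.frame(time_ms = numeric(0), x = numeric(0), y = numeric(0),
                      pupil = numeric(0))
  if (!length(sample_lines)) {
    return(list(left = empty, right = empty, eyes = eyes_declared,
                has_pupil = FALSE))
  }
  toks <- lapply(sample_lines, function(l) {
    f <- split_fields(l)
    f[is_numeric_field(f)]           # drop trailing flag tokens like "..."
  })
  counts <- lengths(toks)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    abort_named("inconsistent sample field count at line %d (%d fields, expected %d)",
                linenos[bad], counts[bad], counts[1])
  }
  nf <- counts[1]
  binocular <- if (length(eyes_declared) == 2L) TRUE
               else if (length(eyes_declared) == 1L) FALSE
               else nf >= 6L
  has_pupil <- if (binocular) nf >= 7L else nf >= 4L
  m <- do.call(rbind, lapply(toks, field_value))
  if (binocular) {
    if (nf < 6L) abort_named("binocular samples need at least 6 fields, got %d", nf)
    left <- data.frame(time_ms = m[, 1], x = m[, 2], y = m[, 3],
                       pupil = if (has_pupil) m[, 4] else NA_real_)
    ro <- if (has_pupil) 5L else 4L
    right <- data.frame(time_ms = m[, 1], x = m[, ro], y = m[, ro + 1L],
                        pupil = if (has_pupil) m[, ro + 2L] else NA_real_)
    eyes <- c("left", "right")
  } else {
    if (nf < 3L) abort_named("monocular samples need at least 3 fields, got %d", nf)
    one <- data.frame(time_ms = m[, 1], x = m[, 2], y = m[, 3],
                      pupil = if (has_pupil) m[, 4] else NA_real_)
    eye <- if (length(eyes_declared) == 1L) eyes_declared else "left"
    if (eye == "right") { left <- empty; right <- one }
    else { left <- one; right <- empty }
    eyes <- eye
  }
  if (nrow(left) > 1L && any(diff(left$time_ms) < 0)) {
    abort_named("sample timestamps decrease within the left-eye stream")
  }
  if (nrow(right) > 1L && any(diff(right$time_ms) < 0)) {
    abort_named("sample timestamps decrease within the right-eye stream")
  }
  list(left = left, right = right, eyes = eyes, has_pupil = has_pupil)
}

#' @export
print.asc_session <- function(x, ...) {
  cat(sprintf("<asc_session> eyes: %s; rate: %g Hz; samples: %d/%d (L/R); events: %d; messages: %d\n",
              paste(x$eyes, collapse = "+"), x$sampling_frequency,
              nrow(x$samples_left), nrow(x$samples_right), nrow(x$events),
              nrow(x$messages)))
  invisible(x)
}

#' Read an ASC file from disk
#'
#' Transparently handles gzip-compressed files (sniffed from the magic
#' bytes); binary EDF files are not supported -- export to ASC first.
#'
#' @param path file path.
#' @return an `asc_session`; see [parse_asc()].
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) abort_named("no such file: %s", path)
  magic <- readBin(path, "raw", n = 2L)
  con <- if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
  on.exit(close(con))
  parse_asc(readLines(con, warn = FALSE))
}

#' Extract the uniformly sampled recording of one eye
#'
#' Projects the per-eye sample stream of a parsed session into a
#' [gaze_recording()]: device milliseconds become seconds (each timestamp
#' divided by 1000 individually, so millisecond precision is preserved
#' exactly), and missing samples stay as missing cells -- rows are never
#' dropped, which would break the uniform sampling contract.
#'
#' @param session an `asc_session` from [parse_asc()].
#' @param eye `"left"` or `"right"`; must be among `session$eyes`.
#' @return a [gaze_recording()] with columns `timestamp`, `x_coordinate`,
#'   `y_coordinate` and, when the device recorded it, `pupil_size`.
#' @export
extract_recording <- function(session, eye) {
  if (!eye %in% session$eyes) {
    abort_named("%s not recorded; available: %s", eye,
                paste(session$eyes, collapse = ", "))
  }
  tbl <- if (eye == "left") session$samples_left else session$samples_right
  data <- data.frame(timestamp = tbl$time_ms / 1000,
                     x_coordinate = tbl$x, y_coordinate = tbl$y)
  cols <- list(
    column_descriptor("timestamp", "Device timestamp", "seconds"),
    column_descriptor("x_coordinate", "Horizontal gaze position", "pixels"),
    column_descriptor("y_coordinate", "Vertical gaze position", "pixels"))
  if (isTRUE(session$has_pupil)) {
    data$pupil_size <- tbl$pupil
    measure <- if (!is.na(session$pupil_measure)) session$pupil_measure else "area"
    cols <- c(cols, list(column_descriptor(
      "pupil_size", sprintf("Pupil %s reported by the device", measure),
      "arbitrary")))
  }
  gaze_recording(data, cols,
                 sampling_frequency = session$sampling_frequency,
                 start_time = 0, recorded_eye = eye,
                 manufacturer = "SR Research",
                 model = "EyeLink")
}

#' Extract the asynchronous event table of one eye
#'
#' Device messages (eye `n/a`), recording start/stop marks, and the
#' fixation/saccade/blink events reported for the requested eye, sorted
#' stably by onset. Onsets and durations are converted to seconds on the same
#' scale as [extract_recording()] timestamps. Messages beginning with `!CAL`
#' are classified as calibration events and passed through verbatim.
#'
#' @inheritParams extract_recording
#' @return an [event_table()] (possibly empty).
#' @export
extract_events <- function(session, eye) {
  rows <- list()
  msgs <- session$messages
  if (nrow(msgs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      onset = msgs$time_ms / 1000, duration = NA_real_,
      event_type = ifelse(startsWith(msgs$text, "!CAL"), "calibration",
                          "message"),
      eye = NA_character_, message = msgs$text, stringsAsFactors = FALSE)
  }
  for (mark in c("start", "stop")) {
    ts <- if (mark == "start") session$start_timestamp else session$end_timestamp
    if (!is.na(ts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = ts / 1000, duration = NA_real_, event_type = mark,
        eye = NA_character_, message = NA_character_, stringsAsFactors = FALSE)
    }
  }
  evs <- session$events
  evs <- evs[evs$eye == eye, , drop = FALSE]
  if (nrow(evs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      onset = evs$start_ms / 1000, duration = evs$duration_ms / 1000,
      event_type = evs$type, eye = evs$eye, message = NA_character_,
      x_start = evs$x0, y_start = evs$y0, x_end = evs$x1, y_end = evs$y1,
      pupil = evs$pupil, amplitude = evs$amplitude,
      peak_velocity = evs$peak_velocity, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(event_table())
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(all_cols, names(r))) r[[m]] <- NA_real_
    r[all_cols]
  })
  event_table(do.call(rbind, rows), columns = event_param_descriptors())
}

event_param_descriptors <- function() {
  list(
    onset = column_descriptor("onset", "Event onset on the OnsetSource timescale", "seconds"),
    duration = column_descriptor("duration", "Event duration", "seconds"),
    event_type = column_descriptor("event_type", "Kind of device event",
      extra = list(Levels = list(message = "device-generated message",
                                 fixation = "gaze fixation reported by the device",
                                 saccade = "saccade reported by the device",
                                 blink = "eyelid closure reported by the device",
                                 start = "recording start", stop = "recording stop",
                                 calibration = "calibration protocol message"))),
    eye = column_descriptor("eye", "Eye the event belongs to"),
    message = column_descriptor("message", "Verbatim device message text"),
    x_start = column_descriptor("x_start", "Gaze x at event start", "pixels"),
    y_start = column_descriptor("y_start", "Gaze y at event start", "pixels"),
    x_end = column_descriptor("x_end", "Gaze x at event end", "pixels"),
    y_end = column_descriptor("y_end", "Gaze y at event end", "pixels"),
    pupil = column_descriptor("pupil", "Mean pupil size during the event", "arbitrary"),
    amplitude = column_descriptor("amplitude", "Saccade amplitude", "degrees"),
    peak_velocity = column_descriptor("peak_velocity", "Saccade peak velocity", "degrees/second"))
}

#' Count the samples of one eye
#' @inheritParams extract_recording
#' @return integer sample count.
#' @export
n_samples <- function(session, eye) {
  if (eye == "left") nrow(session$samples_left) else nrow(session$samples_right)
}
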