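# Rule engine for the eye-tracking subset of BIDS validation.
#
# Rule catalogue (severity fixed per rule):
#   ET01  filename obeys the entity grammar (error); recording labels should
#         use indexed names like eye1/eye2 (warning).
#   ET02  every data file has its sidecar / companion (error).
#   ET03  SamplingFrequency present and > 0 (error).
#   ET04  StartTime present and finite (error).
#   ET05  Columns has timestamp first plus x_coordinate and y_coordinate
#         (error; minimum three columns).
#   ET06  every table row has exactly length(Columns) fields (error).
#   ET07  PhysioType "eyetrack" unlocks mandatories: RecordedEye in
#         {left, right, cyclopean}, SampleCoordinateSystem, and the recording
#         entity in the filename (error).
#   ET08  at most one eye per physio file: no duplicate gaze-coordinate
#         columns, and no two files of one acquisition declaring the same
#         RecordedEye under different recording labels (error).
#   ET09  physioevents sidecar has OnsetSource (a) naming a column of the
#         companion physio sidecar (b) (error).
#   ET10  uniform sampling: |dt - 1/fs| <= 0.01/fs for all consecutive
#         timestamps (error).
#   ET11  event onsets inside the companion recording's timestamp span
#         (warning: pre/post-recording device messages are plausible).
#   ET12  every column beyond the mandatory trio is described by a sidecar
#         metadata object (error).
#   ET13  no header row: the first field of the first line must be numeric
#         (error).

issue <- function(rule_id, severity, path, message, context = NULL) {
  data.frame(rule_id = rule_id, severity = severity, path = path,
             message = message,
             context = if (is.null(context)) NA_character_ else context,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(rule_id = character(0), severity = character(0),
             path = character(0), message = character(0),
             context = character(0), stringsAsFactors = FALSE)
}

bind_issues <- function(...) {
  out <- do.call(rbind, Filter(Negate(is.null), list(...)))
  if (is.null(out)) no_issues() else out
}

# Uniform-sampling tolerance: 1% of the sample period, enough to absorb
# decimal-text rounding while catching any dropped sample (a gap of 2/fs).
ET10_TOL_FRACTION <- 0.01

#' Validate one physio TSVGZ + sidecar JSON pair
#'
#' Applies the per-file rules (ET01, ET03--ET08, ET10, ET12, ET13) and
#' reports every violation -- no fail-fast, so a converter author sees all
#' problems at once.
#'
#' @param tsv,json paths to the data file and its sidecar.
#' @return a data.frame of issues with columns `rule_id`, `severity`,
#'   `path`, `message`, `context`; zero rows means the pair is compliant.
#' @export
validate_physio_pair <- function(tsv, json) {
  issues <- no_issues()
  name_info <- tryCatch(parse_bids_name(basename(tsv)), error = function(e) e)
  if (inherits(name_info, "error")) {
    issues <- bind_issues(issues,
      issue("ET01", "error", tsv, conditionMessage(name_info)))
    name_info <- NULL
  } else if ("recording" %in% names(name_info$entities) &&
             !grepl("^eye[1-9][0-9]*$", name_info$entities[["recording"]])) {
    issues <- bind_issues(issues,
      issue("ET01", "warning", tsv, sprintf(
        "recording label '%s' should use an indexed name like eye1",
        name_info$entities[["recording"]])))
  }
  if (!file.exists(json)) {
    return(bind_issues(issues,
      issue("ET02", "error", tsv, "sidecar JSON file is missing")))
  }
  sc <- tryCatch(read_json_sidecar(json), error = function(e) e)
  if (inherits(sc, "error")) {
    return(bind_issues(issues,
      issue("ET02", "error", json,
            sprintf("sidecar is not readable JSON: %s", conditionMessage(sc)))))
  }

  fs <- sc$SamplingFrequency
  if (is.null(fs) || !is.numeric(fs) || length(fs) != 1L || !is.finite(fs) ||
      fs <= 0) {
    issues <- bind_issues(issues,
      issue("ET03", "error", json,
            "SamplingFrequency must be present and a positive number in Hertz"))
    fs <- NA_real_
  }
  st <- sc$StartTime
  if (is.null(st) || !is.numeric(st) || length(st) != 1L || !is.finite(st)) {
    issues <- bind_issues(issues,
      issue("ET04", "error", json,
            "StartTime must be present and a finite number of seconds"))
  }
  cols <- unlist(sc$Columns)
  if (is.null(cols) || !length(cols)) {
    issues <- bind_issues(issues,
      issue("ET05", "error", json, "Columns list is missing or empty"))
    cols <- character(0)
  } else {
    if (length(cols) < 3L || cols[1] != "timestamp" ||
        !all(c("x_coordinate", "y_coordinate") %in% cols)) {
      issues <- bind_issues(issues,
        issue("ET05", "error", json, paste(
          "a physio recording needs at least three columns:",
          "timestamp (first), x_coordinate and y_coordinate")))
    }
    # ET12: every non-mandatory column fully described
    for (nm in setdiff(cols, MANDATORY_PHYSIO_COLUMNS)) {
      if (!is.list(sc[[nm]])) {
        issues <- bind_issues(issues,
          issue("ET12", "error", json, sprintf(
            "column '%s' is not described by a metadata object in the sidecar",
            nm)))
      }
    }
    # ET08a: duplicate gaze-coordinate columns imply more than one eye
    for (axis in c("x_coordinate", "y_coordinate")) {
      n_axis <- sum(cols == axis | grepl(paste0("^", axis, "_"), cols))
      if (n_axis > 1L) {
        issues <- bind_issues(issues,
          issue("ET08", "error", json, sprintf(
            "more than one %s-like column (%d found): a physio file may hold at most one eye",
            axis, n_axis)))
      }
    }
  }
  if (identical(sc$PhysioType, "eyetrack")) {
    re <- sc$RecordedEye
    if (is.null(re) || !re %in% RECORDED_EYE_VALUES) {
      issues <- bind_issues(issues,
        issue("ET07", "error", json, sprintf(
          "PhysioType 'eyetrack' makes RecordedEye mandatory; allowed values: %s",
          paste(RECORDED_EYE_VALUES, collapse = ", "))))
    }
    if (is.null(sc$SampleCoordinateSystem)) {
      issues <- bind_issues(issues,
        issue("ET07", "error", json,
              "PhysioType 'eyetrack' makes SampleCoordinateSystem mandatory"))
    }
    if (!is.null(name_info) && !"recording" %in% names(name_info$entities)) {
      issues <- bind_issues(issues,
        issue("ET07", "error", tsv,
              "PhysioType 'eyetrack' makes the recording entity mandatory in the filename"))
    }
  }

  lines <- tryCatch(read_tsvgz_lines(tsv), error = function(e) NULL)
  if (is.null(lines)) {
    return(bind_issues(issues,
      issue("ET02", "error", tsv, "data file is not readable as gzip TSV")))
  }
  fields <- split_tsv_lines(lines)
  widths <- lengths(fields)
  if (length(cols) && length(widths)) {
    bad <- which(widths != length(cols))
    if (length(bad)) {
      issues <- bind_issues(issues,
        issue("ET06", "error", tsv, sprintf(
          "row %d has %d fields but the sidecar Columns lists %d",
          bad[1], widths[bad[1]], length(cols)),
          context = sprintf("row %d", bad[1])))
    }
  }
  if (length(fields)) {
    first <- fields[[1]][1]
    if (is.na(suppressWarnings(as.numeric(first)))) {
      issues <- bind_issues(issues,
        issue("ET13", "error", tsv, sprintf(
          "first field of the first row ('%s') is not numeric: physio files must not contain a header row",
          first)))
    } else if (length(cols) && cols[1] == "timestamp" && is.finite(fs) &&
               all(widths == length(cols))) {
      ts <- parse_number(vapply(fields, `[[`, character(1), 1L))
      if (!anyNA(ts) && length(ts) > 1L) {
        dt <- diff(ts)
        tol <- ET10_TOL_FRACTION / fs
        bad <- which(abs(dt - 1 / fs) > tol)
        if (length(bad)) {
          issues <- bind_issues(issues,
            issue("ET10", "error", tsv, sprintf(
              "sampling is not uniform: gap of %g s between rows %d and %d (expected %g s)",
              dt[bad[1]], bad[1], bad[1] + 1L, 1 / fs),
              context = sprintf("rows %d-%d", bad[1], bad[1] + 1L)))
        }
      }
    }
  }
  issues
}

#' Validate one physioevents pair against its companion physio sidecar
#'
#' Checks OnsetSource presence (ET09a), that it names a column of the
#' companion physio sidecar (ET09b), row widths (ET06), column description
#' (ET12), headerlessness (ET13), and -- as a warning -- that onsets fall
#' inside the companion recording's timestamp span (ET11).
#'
#' @param tsv,json the physioevents pair.
#' @param companion_physio_json sidecar of the physio file sharing the same
#'   entities; `NULL` when absent (an ET02-class error).
#' @param companion_physio_tsv optional companion data file, used for the
#'   ET11 span check.
#' @return issue data.frame as in [validate_physio_pair()].
#' @export
validate_physioevents_pair <- function(tsv, json, companion_physio_json,
                                       companion_physio_tsv = NULL) {
  issues <- no_issues()
  name_info <- tryCatch(parse_bids_name(basename(tsv)), error = function(e) e)
  if (inherits(name_info, "error")) {
    issues <- bind_issues(issues,
      issue("ET01", "error", tsv, conditionMessage(name_info)))
  }
  if (!file.exists(json)) {
    return(bind_issues(issues,
      issue("ET02", "error", tsv, "sidecar JSON file is missing")))
  }
  sc <- tryCatch(read_json_sidecar(json), error = function(e) e)
  if (inherits(sc, "error")) {
    return(bind_issues(issues,
      issue("ET02", "error", json,
            sprintf("sidecar is not readable JSON: %s", conditionMessage(sc)))))
  }
  if (is.null(companion_physio_json) || !file.exists(companion_physio_json)) {
    issues <- bind_issues(issues,
      issue("ET02", "error", tsv,
            "no companion physio sidecar shares this file's entities"))
    companion <- NULL
  } else {
    companion <- tryCatch(read_json_sidecar(companion_physio_json),
                          error = function(e) NULL)
  }
  os <- sc$OnsetSource
  if (is.null(os) || !nzchar(os)) {
    issues <- bind_issues(issues,
      issue("ET09", "error", json,
            "OnsetSource is mandatory in physioevents sidecars"))
    os <- NULL
  } else if (!is.null(companion)) {
    comp_cols <- unlist(companion$Columns)
    if (!os %in% comp_cols) {
      issues <- bind_issues(issues,
        issue("ET09", "error", json, sprintf(
          "OnsetSource '%s' is not among the companion physio Columns (%s)",
          os, paste(comp_cols, collapse = ", "))))
    }
  }
  cols <- unlist(sc$Columns)
  lines <- tryCatch(read_tsvgz_lines(tsv), error = function(e) NULL)
  if (is.null(lines)) {
    return(bind_issues(issues,
      issue("ET02", "error", tsv, "data file is not readable as gzip TSV")))
  }
  fields <- split_tsv_lines(lines)
  widths <- lengths(fields)
  if (length(cols)) {
    bad <- which(widths != length(cols))
    if (length(bad)) {
      issues <- bind_issues(issues,
        issue("ET06", "error", tsv, sprintf(
          "row %d has %d fields but the sidecar Columns lists %d",
          bad[1], widths[bad[1]], length(cols))))
    }
    for (nm in setdiff(cols, "onset")) {
      if (!is.list(sc[[nm]])) {
        issues <- bind_issues(issues,
          issue("ET12", "error", json, sprintf(
            "column '%s' is not described by a metadata object in the sidecar",
            nm)))
      }
    }
  }
  if (length(fields)) {
    first <- fields[[1]][1]
    if (is.na(suppressWarnings(as.numeric(first)))) {
      issues <- bind_issues(issues,
        issue("ET13", "error", tsv,
              "first field of the first row is not numeric: physioevents files must not contain a header row"))
    }
  }
  # ET11: onsets inside the companion recording span (warning)
  if (!is.null(companion_physio_tsv) && file.exists(companion_physio_tsv) &&
      identical(os, "timestamp") && length(fields) &&
      all(widths == widths[1])) {
    comp_ts <- parse_number(vapply(
      split_tsv_lines(read_tsvgz_lines(companion_physio_tsv)),
      `[[`, character(1), 1L))
    onsets <- parse_number(vapply(fields, `[[`, character(1), 1L))
    if (length(comp_ts) && !anyNA(comp_ts)) {
      out_of_span <- onsets < min(comp_ts) | onsets > max(comp_ts)
      if (any(out_of_span, na.rm = TRUE)) {
        k <- which(out_of_span)[1]
        issues <- bind_issues(issues,
          issue("ET11", "warning", tsv, sprintf(
            "event onset %g s lies outside the recording span [%g, %g] s",
            onsets[k], min(comp_ts), max(comp_ts))))
      }
    }
  }
  issues
}

find_companion <- function(events_tsv) {
  bp <- tryCatch(parse_bids_name(basename(events_tsv)), error = function(e) NULL)
  if (is.null(bp)) return(list(json = NULL, tsv = NULL))
  base <- format_bids_stem(bp$entities, "physio")
  dir <- dirname(events_tsv)
  list(json = file.path(dir, paste0(base, ".json")),
       tsv = file.path(dir, paste0(base, ".tsv.gz")))
}

#' Validate every eye-tracking file pair under a BIDS root
#'
#' Walks the tree for `*_physio.tsv.gz` and `*_physioevents.tsv.gz` files,
#' applies all rules (ET01--ET13) to each pair, and adds the
#' acquisition-level single-eye check (ET08: two files of one acquisition
#' must not declare the same `RecordedEye` under different recording labels).
#' The issue list is deterministically ordered by path, then rule id.
#'
#' @param root dataset root directory.
#' @return issue data.frame; zero rows means the dataset is compliant.
#' @export
validate_dataset <- function(root) {
  if (!dir.exists(root)) abort_named("not a directory: %s", root)
  all_files <- list.files(root, recursive = TRUE, full.names = TRUE)
  physio_tsv <- sort(all_files[grepl("_physio\\.tsv\\.gz$", all_files)])
  events_tsv <- sort(all_files[grepl("_physioevents\\.tsv\\.gz$", all_files)])
  orphan_json <- sort(all_files[grepl("_physio\\.json$", all_files)])

  issues <- no_issues()
  for (tsv in physio_tsv) {
    json <- sub("\\.tsv\\.gz$", ".json", tsv)
    issues <- bind_issues(issues, validate_physio_pair(tsv, json))
  }
  for (json in orphan_json) {
    tsv <- sub("\\.json$", ".tsv.gz", json)
    if (!file.exists(tsv)) {
      issues <- bind_issues(issues,
        issue("ET02", "error", json, "sidecar has no matching physio data file"))
    }
  }
  for (tsv in events_tsv) {
    json <- sub("\\.tsv\\.gz$", ".json", tsv)
    comp <- find_companion(tsv)
    issues <- bind_issues(issues,
      validate_physioevents_pair(tsv, json, comp$json, comp$tsv))
  }

  # ET08b: within one acquisition (same directory + entities minus recording),
  # each RecordedEye may appear under at most one recording label.
  acq_key <- character(0); eye_seen <- character(0); rec_seen <- character(0)
  files_seen <- character(0)
  for (tsv in physio_tsv) {
    json <- sub("\\.tsv\\.gz$", ".json", tsv)
    bp <- tryCatch(parse_bids_name(basename(tsv)), error = function(e) NULL)
    sc <- tryCatch(read_json_sidecar(json), error = function(e) NULL)
    if (is.null(bp) || is.null(sc) || is.null(sc$RecordedEye)) next
    ents <- bp$entities[setdiff(names(bp$entities), "recording")]
    key <- paste0(dirname(tsv), "|",
                  paste(names(ents), ents, sep = "-", collapse = "_"))
    rec <- bp$entities[["recording"]] %||% ""
    dup <- which(acq_key == key & eye_seen == sc$RecordedEye & rec_seen != rec)
    if (length(dup)) {
      issues <- bind_issues(issues,
        issue("ET08", "error", tsv, sprintf(
          "RecordedEye '%s' already declared by %s under a different recording label",
          sc$RecordedEye, basename(files_seen[dup[1]]))))
    }
    acq_key <- c(acq_key, key); eye_seen <- c(eye_seen, sc$RecordedEye)
    rec_seen <- c(rec_seen, rec); files_seen <- c(files_seen, tsv)
  }

  if (nrow(issues)) {
    issues <- issues[order(issues$path, issues$rule_id), , drop = FALSE]
    rownames(issues) <- NULL
  }
  issues
}
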