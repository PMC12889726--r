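# Serialization: start-time arithmetic, layout planning, sidecar content,
# TSVGZ/JSON round trips, byte determinism, conversion fan-out.

test_that("compute_start_time implements the signed offset definition", {
  expect_equal(compute_start_time(10.0, 10.0), 0.0)
  expect_equal(compute_start_time(7.5, 10.0), -2.5)
  expect_equal(compute_start_time(12.25, 10.0), 2.25)
  expect_error(compute_start_time(NA_real_, 1), "finite")
})

test_that("plan_layout places physio files in the modality folder", {
  expect_equal(plan_layout(acquisition_context("01", "t", main_modality = "func")),
               "sub-01/func")
  expect_equal(plan_layout(acquisition_context("02", "t", session = "01",
                                               main_modality = "none")),
               "sub-02/ses-01/beh")
  expect_equal(plan_layout(acquisition_context("01", "t", main_modality = "meg")),
               "sub-01/meg")
  expect_error(acquisition_context("01", "t", main_modality = "spect"),
               "func, eeg, meg, beh, none")
})

test_that("build_physio_sidecar fills the eyetrack metadata contract", {
  s <- parse_asc(hand_asc())
  rec <- extract_recording(s, "left")
  ctx <- acquisition_context("01", "visualSearch")
  sc <- build_physio_sidecar(rec, ctx)
  expect_equal(sc$SamplingFrequency, 1000)
  expect_equal(sc$PhysioType, "eyetrack")
  expect_equal(sc$RecordedEye, "left")
  expect_equal(sc$Columns,
               c("timestamp", "x_coordinate", "y_coordinate", "pupil_size"))
  expect_false(is.null(sc$SampleCoordinateSystem))
  expect_true("pupil_size" %in% names(sc$column_metadata))

  # cyclopean stream carries its own RecordedEye value
  rec2 <- rec; rec2$recorded_eye <- "cyclopean"
  expect_equal(build_physio_sidecar(rec2, ctx)$RecordedEye, "cyclopean")
})

test_that("described extra columns survive the sidecar and validate clean", {
  s <- parse_asc(hand_asc())
  rec <- extract_recording(s, "left")
  rec$data$gaze_velocity <- seq_len(nrow(rec$data)) * 0.1
  rec$columns <- c(rec$columns, list(column_descriptor(
    "gaze_velocity", "Instantaneous gaze speed", "pixels/second")))
  ctx <- acquisition_context("01", "visualSearch")
  sc <- build_physio_sidecar(rec, ctx)
  expect_true("gaze_velocity" %in% names(sc$column_metadata))
  root <- tempfile()
  p <- bids_path(c(sub = "01", task = "visualSearch", recording = "eye1"),
                 "physio", ".tsv.gz", datatype_dir = "sub-01/beh")
  write_physio_pair(rec, sc, p, root)
  iss <- validate_physio_pair(
    file.path(root, "sub-01/beh",
              "sub-01_task-visualSearch_recording-eye1_physio.tsv.gz"),
    file.path(root, "sub-01/beh",
              "sub-01_task-visualSearch_recording-eye1_physio.json"))
  expect_equal(nrow(iss), 0L)
})

test_that("physio writer emits headerless rows and n/a for missing cells", {
  root <- tempfile()
  rec <- gaze_recording(
    data.frame(timestamp = c(0, 0.002), x_coordinate = c(1.5, NA),
               y_coordinate = c(2, 3)),
    sampling_frequency = 500, recorded_eye = "left")
  sc <- build_physio_sidecar(rec, acquisition_context("01", "t"))
  p <- bids_path(c(sub = "01", task = "t", recording = "eye1"),
                 "physio", ".tsv.gz")
  files <- write_physio_pair(rec, sc, p, root)
  lines <- etbids:::read_tsvgz_lines(files[1])
  expect_equal(lines, c("0\t1.5\t2", "0.002\tn/a\t3"))
  # and n/a comes back as a missing cell, not the string
  back <- read_physio_pair(files[1], files[2])
  expect_true(is.na(back$data$x_coordinate[2]))
  expect_equal(back$data$timestamp, rec$data$timestamp)
})

test_that("writers refuse to clobber without overwrite and tag width errors", {
  tree <- make_clean_tree(seed = 5, eyes = "left")
  expect_error(convert_session(tree$session, tree$ctx, tree$root),
               "overwrite")
  tsv <- tree_file(tree, "eye1_physio\\.tsv\\.gz$")
  edit_tsvgz(tsv, function(l) c(l, "1\t2"))
  expect_error(
    read_physio_pair(tsv, sub("\\.tsv\\.gz$", ".json", tsv)), "ET06")
})

test_that("physioevents serialization uses the fixed column order", {
  tab <- event_table(data.frame(
    onset = 5.0, duration = NA_real_, event_type = "message",
    eye = NA_character_, message = "TRIALID 1", stringsAsFactors = FALSE))
  sc <- events_sidecar("timestamp", column_metadata =
                         etbids:::event_param_descriptors()[1:5])
  root <- tempfile()
  p <- bids_path(c(sub = "01", task = "t", recording = "eye1"),
                 "physioevents", ".tsv.gz")
  files <- write_physioevents_pair(tab, sc, p, root)
  expect_equal(etbids:::read_tsvgz_lines(files[1]),
               "5\tn/a\tmessage\tn/a\tTRIALID 1")
  meta <- etbids:::read_json_sidecar(files[2])
  expect_equal(unlist(meta$Columns),
               c("onset", "duration", "event_type", "eye", "message"))
  expect_equal(meta$OnsetSource, "timestamp")

  # empty table: zero-line TSVGZ plus a valid sidecar
  files2 <- write_physioevents_pair(
    event_table(), sc,
    bids_path(c(sub = "02", task = "t", recording = "eye1"),
              "physioevents", ".tsv.gz"), root)
  expect_length(etbids:::read_tsvgz_lines(files2[1]), 0L)
  expect_equal(etbids:::read_json_sidecar(files2[2])$OnsetSource, "timestamp")
})

test_that("undeclared event parameter columns are rejected by name", {
  tab <- event_table(data.frame(
    onset = 1, duration = NA_real_, event_type = "other",
    eye = NA_character_, message = NA_character_, mystery_param = 3.3,
    stringsAsFactors = FALSE))
  p <- bids_path(c(sub = "01", task = "t", recording = "eye1"),
                 "physioevents", ".tsv.gz")
  expect_error(
    write_physioevents_pair(tab, events_sidecar("timestamp"), p, tempfile()),
    "mystery_param")
})

test_that("write/read round-trips are exact for simulated recordings", {
  for (seed in 1:6) {
    tree <- make_clean_tree(seed = seed, eyes = if (seed %% 2) "left" else
      c("left", "right"))
    for (eye_tag in if (seed %% 2) "eye1" else c("eye1", "eye2")) {
      tsv <- tree_file(tree, paste0(eye_tag, "_physio\\.tsv\\.gz$"))
      json <- sub("\\.tsv\\.gz$", ".json", tsv)
      back <- read_physio_pair(tsv, json)
      eye <- if (eye_tag == "eye1") "left" else "right"
      orig <- extract_recording(tree$session, eye)
      expect_identical(back$data, orig$data)
      expect_equal(back$sampling_frequency, orig$sampling_frequency)
      expect_equal(back$recorded_eye, eye)

      etsv <- tree_file(tree, paste0(eye_tag, "_physioevents\\.tsv\\.gz$"))
      ejson <- sub("\\.tsv\\.gz$", ".json", etsv)
      back_ev <- read_physioevents_pair(etsv, ejson)
      orig_ev <- extract_events(tree$session, eye)
      expect_equal(nrow(back_ev$table), nrow(orig_ev))
      expect_equal(back_ev$table$onset, orig_ev$onset)
      expect_equal(back_ev$table$event_type, orig_ev$event_type)
    }
  }
})

test_that("conversion fan-out matches the recorded eyes", {
  bino <- make_clean_tree(seed = 2, eyes = c("left", "right"))
  expect_length(bino$files, 8L)
  expect_length(grep("recording-eye1", bino$files), 4L)
  expect_length(grep("recording-eye2", bino$files), 4L)

  mono <- make_clean_tree(seed = 2, eyes = "left", modality = "none")
  expect_length(mono$files, 4L)
  expect_true(all(grepl("recording-eye1", mono$files)))
  expect_true(all(grepl("/beh/", mono$files)))
  expect_true(file.exists(file.path(mono$root, "dataset_description.json")))
})

test_that("identical inputs produce byte-identical files", {
  t1 <- make_clean_tree(seed = 9, root = tempfile())
  t2 <- make_clean_tree(seed = 9, root = tempfile())
  for (i in seq_along(t1$files)) {
    b1 <- readBin(t1$files[i], "raw", file.info(t1$files[i])$size)
    b2 <- readBin(t2$files[i], "raw", file.info(t2$files[i])$size)
    expect_identical(b1, b2)
  }
})
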