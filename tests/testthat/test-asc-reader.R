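# ASC dialect parsing: line classification, per-eye streams, event layouts,
# missing samples, and recovery of simulator ground truth.

test_that("a single MSG line parses to one message and no samples", {
  s <- parse_asc("MSG\t5000 TRIALID 1")
  expect_equal(nrow(s$messages), 1L)
  expect_equal(s$messages$time_ms, 5000)
  expect_equal(s$messages$text, "TRIALID 1")
  expect_equal(nrow(s$samples_left) + nrow(s$samples_right), 0L)
})

test_that("the documented monocular sample grammar is applied", {
  s <- parse_asc(c("SAMPLES\tGAZE\tLEFT\tRATE\t1000.00",
                   "5000\t512.0\t384.0\t1200.0\t..."))
  expect_equal(s$sampling_frequency, 1000)
  expect_equal(s$eyes, "left")
  expect_equal(nrow(s$samples_left), 1L)
  expect_equal(unlist(s$samples_left[1, ]),
               c(time_ms = 5000, x = 512, y = 384, pupil = 1200))
})

test_that("EFIX lines follow the documented field layout", {
  s <- parse_asc("EFIX L   5000\t5200\t200\t  512.0\t  384.0\t  1180.0")
  ev <- extract_events(s, "left")
  fix <- ev[ev$event_type == "fixation", ]
  expect_equal(nrow(fix), 1L)
  expect_equal(fix$onset, 5.0)
  expect_equal(fix$duration, 0.2)
  expect_equal(fix$eye, "left")
  expect_equal(fix$x_start, 512)
  expect_equal(fix$pupil, 1180)
})

test_that("every E-event duration equals end minus start of its line", {
  sim <- simulate_session(quick_cfg(seed = 11))
  s <- parse_asc(render_asc(sim))
  expect_true(all(abs(s$events$duration_ms -
                        (s$events$end_ms - s$events$start_ms)) < 1e-6))
})

test_that("a blink blanks exactly the samples inside the device EBLINK span", {
  s <- parse_asc(hand_asc(n = 1000, blink_start = 5100, blink_len = 120))
  blink <- s$events[s$events$type == "blink", ]
  expect_equal(nrow(blink), 1L)
  # oracle: count samples whose timestamp falls in the ground-truth interval
  in_span <- s$samples_left$time_ms >= 5100 & s$samples_left$time_ms < 5220
  expect_equal(sum(in_span), 120L)
  expect_true(all(is.na(s$samples_left$x[in_span])))
  expect_true(all(!is.na(s$samples_left$x[!in_span])))
  rec <- extract_recording(s, "left")
  expect_equal(sum(is.na(rec$data$x_coordinate)), 120L)
})

test_that("binocular rows split into per-eye streams of equal length", {
  sim <- simulate_session(quick_cfg(seed = 3, duration = 2))
  s <- parse_asc(render_asc(sim))
  expect_setequal(s$eyes, c("left", "right"))
  expect_equal(n_samples(s, "left"), 1000L)
  expect_equal(n_samples(s, "right"), 1000L)
  # conservation: extraction never drops rows
  expect_equal(nrow(extract_recording(s, "left")$data), 1000L)
  expect_equal(nrow(extract_recording(s, "right")$data), 1000L)
})

test_that("extract_recording projects columns and converts ms to seconds", {
  s <- parse_asc(hand_asc())
  rec <- extract_recording(s, "left")
  expect_equal(names(rec$data),
               c("timestamp", "x_coordinate", "y_coordinate", "pupil_size"))
  expect_equal(rec$recorded_eye, "left")
  expect_equal(rec$data$timestamp[1], 5.0)
  expect_equal(diff(rec$data$timestamp[1:2]), 0.001)
  expect_error(extract_recording(s, "right"),
               "right not recorded; available: left")
})

test_that("extract_events filters by eye, classifies and sorts stably", {
  sim <- simulate_session(quick_cfg(seed = 7))
  s <- parse_asc(render_asc(sim))
  for (eye in c("left", "right")) {
    ev <- extract_events(s, eye)
    expect_true(all(diff(ev$onset) >= 0))
    counts <- table(ev$event_type)
    expect_equal(unname(counts["fixation"]), nrow(sim$truth$fixations))
    expect_equal(unname(counts["saccade"]), nrow(sim$truth$saccades))
    if (nrow(sim$truth$blinks)) {
      expect_equal(unname(counts["blink"]), nrow(sim$truth$blinks))
    }
    expect_equal(unname(counts["message"]), nrow(sim$truth$messages))
    other_eye <- setdiff(c("left", "right"), eye)
    expect_false(other_eye %in% ev$eye)
  }
  expect_equal(nrow(extract_events(parse_asc("MSG\t1 x"), "left")), 1L)
})

test_that("unknown lines are counted, never fatal; empty input is rejected", {
  s <- parse_asc(c("SAMPLES\tGAZE\tLEFT\tRATE\t500.00",
                   "GIBBERISH LINE", "ANOTHER ONE"))
  expect_equal(s$n_unknown, 2L)
  expect_error(parse_asc(c("GIBBERISH", "MORE")), "not an ASC file")
  expect_error(parse_asc(character(0)), "not an ASC file")
})

test_that("inconsistent sample field counts name the offending line", {
  expect_error(
    parse_asc(c("SAMPLES\tGAZE\tLEFT\tRATE\t1000.00",
                "5000\t512.0\t384.0\t1200.0",
                "5001\t512.0\t384.0")),
    "line 3")
})

test_that("a missing RATE field falls back to the sample spacing", {
  expect_warning(
    s <- parse_asc(c("SAMPLES\tGAZE\tLEFT",
                     sprintf("%d\t512.0\t384.0\t1200.0", 5000:5019))),
    "inferred")
  expect_equal(s$sampling_frequency, 1000)
})

test_that("gzip-compressed ASC files are sniffed and read", {
  path <- tempfile(fileext = ".asc.gz")
  con <- gzfile(path, "wb")
  writeLines(hand_asc(n = 50), con)
  close(con)
  s <- read_asc(path)
  expect_equal(nrow(s$samples_left), 50L)
})
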