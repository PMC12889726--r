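# Generative model: determinism, sample counts, timeline tiling, blink
# conservation, ASC round trip.

test_that("duration times rate gives the exact per-eye sample count", {
  sim <- simulate_session(quick_cfg(seed = 1, duration = 2,
                                    sampling_frequency = 500))
  expect_equal(nrow(sim$samples$left), 1000L)
  expect_equal(nrow(sim$samples$right), 1000L)
})

test_that("degenerate config yields a constant trace", {
  cfg <- sim_config(duration = 1, sampling_frequency = 250, eyes = "left",
                    noise_sd = 0, blink_rate = 0,
                    fixation_shape = 1e6, fixation_scale = 1,  # one long fixation
                    pupil_drift_amplitude = 0, seed = 2)
  sim <- simulate_session(cfg)
  expect_equal(nrow(sim$truth$fixations), 1L)
  expect_equal(nrow(sim$truth$blinks), 0L)
  expect_length(unique(sim$samples$left$x), 1L)
  expect_length(unique(sim$samples$left$y), 1L)
  expect_length(unique(round(sim$samples$left$pupil, 6)), 1L)
})

test_that("the same seed reproduces the session exactly", {
  s1 <- simulate_session(quick_cfg(seed = 33))
  s2 <- simulate_session(quick_cfg(seed = 33))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$samples, s2$samples)
  s3 <- simulate_session(quick_cfg(seed = 34))
  expect_false(identical(s1$samples, s3$samples))
})

test_that("infeasible blink configuration is rejected", {
  expect_error(sim_config(duration = 0.1, blink_duration_range = c(100, 300)),
               "longer than the session")
})

test_that("fixations and saccades alternate and tile the timeline", {
  for (seed in 1:5) {
    sim <- simulate_session(quick_cfg(seed = seed, duration = 3))
    fx <- sim$truth$fixations; sc <- sim$truth$saccades
    # alternation: saccade k starts where fixation k ends
    expect_equal(sc$start, fx$end[seq_len(nrow(sc))], tolerance = 1e-9)
    expect_equal(fx$start[-1], sc$end[seq_len(nrow(fx) - 1)],
                 tolerance = 1e-9)
    covered <- sum(fx$end - fx$start) + sum(sc$end - sc$start)
    expect_equal(covered, sim$cfg$duration,
                 tolerance = 1 / sim$cfg$sampling_frequency)
    expect_true(all(sim$truth$blinks$start >= 0 &
                      sim$truth$blinks$end <= sim$cfg$duration))
  }
})

test_that("each blink produces exactly one missing-data gap", {
  sim <- simulate_session(quick_cfg(seed = 8, duration = 5, eyes = "left",
                                    blink_rate = 30))
  x <- sim$samples$left$x
  gaps <- rle(is.na(x))
  expect_equal(sum(gaps$values), nrow(sim$truth$blinks))
})

test_that("rendered ASC parses back to the simulated counts", {
  for (seed in c(1, 21, 101)) {
    cfg <- quick_cfg(seed = seed, duration = 2)
    sim <- simulate_session(cfg)
    s <- parse_asc(render_asc(sim))
    expect_equal(s$sampling_frequency, cfg$sampling_frequency)
    expect_setequal(s$eyes, cfg$eyes)
    expect_equal(n_samples(s, "left"), nrow(sim$samples$left))
    for (eye in cfg$eyes) {
      ev <- s$events[s$events$eye == eye, ]
      expect_equal(sum(ev$type == "fixation"), nrow(sim$truth$fixations))
      expect_equal(sum(ev$type == "saccade"), nrow(sim$truth$saccades))
      expect_equal(sum(ev$type == "blink"), nrow(sim$truth$blinks))
    }
    expect_equal(nrow(s$messages), nrow(sim$truth$messages))
  }
})

test_that("header-only ASC renders and parses to an empty session", {
  cfg <- sim_config(duration = 1, sampling_frequency = 500, eyes = "left",
                    blink_rate = 0, n_trial_messages = 0, seed = 1)
  sim <- simulate_session(cfg)
  sim$samples$left <- sim$samples$left[0, ]
  sim$truth$fixations <- sim$truth$fixations[0, ]
  sim$truth$saccades <- sim$truth$saccades[0, ]
  sim$truth$blinks <- sim$truth$blinks[0, ]
  asc <- render_asc(sim)
  expect_error(s <- parse_asc(asc), NA)
  expect_equal(nrow(s$samples_left), 0L)
  expect_equal(nrow(s$events), 0L)
})

test_that("make_fixture_dataset builds a validating tree with a manifest", {
  root <- tempfile()
  cfg <- quick_cfg(seed = 40, duration = 1)
  ctx <- acquisition_context("01", "visualSearch", main_modality = "func")
  res <- make_fixture_dataset(cfg, 2, ctx, root)
  expect_length(res$files, 16L)   # 2 subjects x 8 binocular files
  expect_true(file.exists(file.path(root, "ground_truth_manifest.json")))
  iss <- validate_dataset(root)
  expect_equal(nrow(iss[iss$severity == "error", ]), 0L)
  # distinct seeds give distinct traces, identical structure
  r1 <- read_physio_pair(
    file.path(root, "sub-01/func/sub-01_task-visualSearch_recording-eye1_physio.tsv.gz"),
    file.path(root, "sub-01/func/sub-01_task-visualSearch_recording-eye1_physio.json"))
  r2 <- read_physio_pair(
    file.path(root, "sub-02/func/sub-02_task-visualSearch_recording-eye1_physio.tsv.gz"),
    file.path(root, "sub-02/func/sub-02_task-visualSearch_recording-eye1_physio.json"))
  expect_equal(nrow(r1$data), nrow(r2$data))
  expect_false(identical(r1$data$x_coordinate, r2$data$x_coordinate))
})
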