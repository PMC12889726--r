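# Generative model of eye-tracking sessions: alternating fixations and
# saccades over a screen, Poisson blinks that blank the samples, slow
# sinusoidal pupil drift, plus experiment trigger messages. Ground truth is
# kept alongside the rendered samples so parsers and converters can be tested
# end to end without any real recording.

#' Configuration of a simulated eye-tracking session
#'
#' Defaults are package choices of plausible magnitude, not measurements of
#' any particular device or study: median fixations around 200 ms
#' (Gamma(shape 7, scale 30 ms)), 15 blinks per minute of 100--300 ms,
#' 0.5 px positional noise, saccade durations on the conventional
#' main-sequence approximation `2.2 * amplitude_deg + 21` ms.
#'
#' @param duration session length in seconds.
#' @param sampling_frequency sampling rate in Hz (250, 500, 1000 or 2000).
#' @param eyes character subset of `c("left", "right")`.
#' @param screen `c(width, height)` in pixels.
#' @param fixation_shape,fixation_scale Gamma parameters of fixation
#'   durations, scale in ms.
#' @param blink_rate blinks per minute.
#' @param blink_duration_range `c(min, max)` blink duration in ms.
#' @param pupil_baseline,pupil_drift_amplitude pupil size baseline and slow
#'   drift amplitude, device arbitrary units.
#' @param pupil_drift_period period of the sinusoidal pupil drift, seconds.
#' @param noise_sd Gaussian positional noise during fixations, pixels.
#' @param px_per_deg screen scale used to convert saccade amplitudes to
#'   visual degrees.
#' @param n_trial_messages number of `TRIALID` trigger messages, evenly
#'   spaced over the session.
#' @param start_timestamp device time of the first sample, ms.
#' @param seed integer seed; the whole session is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration = 10, sampling_frequency = 1000,
                       eyes = c("left", "right"), screen = c(1024, 768),
                       fixation_shape = 7, fixation_scale = 30,
                       blink_rate = 15, blink_duration_range = c(100, 300),
                       pupil_baseline = 1000, pupil_drift_amplitude = 50,
                       pupil_drift_period = 20, noise_sd = 0.5,
                       px_per_deg = 35, n_trial_messages = 5,
                       start_timestamp = 1000000, seed = 1) {
  if (duration <= 0) abort_named("duration must be positive")
  if (!sampling_frequency %in% c(250, 500, 1000, 2000)) {
    abort_named("sampling_frequency must be one of 250, 500, 1000, 2000")
  }
  eyes <- match.arg(eyes, c("left", "right"), several.ok = TRUE)
  if (any(blink_duration_range <= 0) || diff(blink_duration_range) < 0) {
    abort_named("blink_duration_range must be positive and ordered")
  }
  if (blink_duration_range[2] / 1000 > duration) {
    abort_named("blinks (%g ms max) cannot be longer than the session (%g s)",
                blink_duration_range[2], duration)
  }
  if (fixation_shape <= 0 || fixation_scale <= 0 || blink_rate < 0 ||
      noise_sd < 0) {
    abort_named("rates and durations must be positive")
  }
  structure(list(duration = duration,
                 sampling_frequency = sampling_frequency, eyes = eyes,
                 screen = screen, fixation_shape = fixation_shape,
                 fixation_scale = fixation_scale, blink_rate = blink_rate,
                 blink_duration_range = blink_duration_range,
                 pupil_baseline = pupil_baseline,
                 pupil_drift_amplitude = pupil_drift_amplitude,
                 pupil_drift_period = pupil_drift_period,
                 noise_sd = noise_sd, px_per_deg = px_per_deg,
                 n_trial_messages = n_trial_messages,
                 start_timestamp = start_timestamp, seed = seed),
            class = "sim_config")
}

# Saccade duration from amplitude: conventional main-sequence approximation.
saccade_duration_ms <- function(amplitude_deg) 2.2 * amplitude_deg + 21

#' Simulate one eye-tracking session
#'
#' Draws an alternating fixation/saccade scanpath (fixation targets uniform
#' on the screen, saccades linearly interpolated over their main-sequence
#' duration), overlays Poisson-count blinks that blank gaze and pupil, adds
#' Gaussian noise during fixations and a slow sinusoidal pupil drift. Both
#' eyes share the scanpath (a fixed 2 px horizontal disparity and independent
#' noise distinguish them). Fully reproducible from `cfg$seed`; the random
#' stream is local, global RNG state is restored on exit.
#'
#' @param cfg a [sim_config()].
#' @return a list with `truth` (fixations, saccades, blinks, messages --
#'   times in seconds relative to session start) and `samples` (named list
#'   per eye: data.frame `time_ms, x, y, pupil`), plus the `cfg`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  dur_ms <- cfg$duration * 1000
  # Alternating fixation / saccade timeline, truncated at session end
  fix <- list(); sac <- list()
  t <- 0
  pos <- c(runif(1, 0, cfg$screen[1]), runif(1, 0, cfg$screen[2]))
  while (t < dur_ms) {
    fdur <- rgamma(1, shape = cfg$fixation_shape, scale = cfg$fixation_scale)
    f_end <- min(t + fdur, dur_ms)
    fix[[length(fix) + 1L]] <- c(start = t, end = f_end,
                                 x = pos[1], y = pos[2])
    t <- f_end
    if (t >= dur_ms) break
    target <- c(runif(1, 0, cfg$screen[1]), runif(1, 0, cfg$screen[2]))
    amp_px <- sqrt(sum((target - pos)^2))
    amp_deg <- amp_px / cfg$px_per_deg
    sdur <- saccade_duration_ms(amp_deg)
    if (t + sdur >= dur_ms) {
      # a saccade would overrun the session: extend the final fixation so
      # fixations and saccades tile the timeline exactly
      fix[[length(fix)]]["end"] <- dur_ms
      break
    }
    sac[[length(sac) + 1L]] <- c(start = t, end = t + sdur,
                                 x0 = pos[1], y0 = pos[2],
                                 x1 = target[1], y1 = target[2],
                                 amplitude = amp_deg,
                                 peak_velocity = 2 * amp_deg / (sdur / 1000))
    t <- t + sdur
    pos <- target
  }
  fixations <- as.data.frame(do.call(rbind, fix))
  saccades <- if (length(sac)) as.data.frame(do.call(rbind, sac)) else
    data.frame(start = numeric(0), end = numeric(0), x0 = numeric(0),
               y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
               amplitude = numeric(0), peak_velocity = numeric(0))

  # Blinks: Poisson count at blink_rate per minute, uniform placement,
  # non-overlapping and separated by at least 3 sample periods so each blink
  # is one distinct missing-data gap.
  n_blinks <- rpois(1, cfg$blink_rate * cfg$duration / 60)
  min_sep <- 3 * 1000 / cfg$sampling_frequency
  blinks <- data.frame(start = numeric(0), end = numeric(0))
  tries <- 0
  while (nrow(blinks) < n_blinks && tries < 1000) {
    tries <- tries + 1
    bdur <- runif(1, cfg$blink_duration_range[1], cfg$blink_duration_range[2])
    bstart <- runif(1, min_sep, dur_ms - bdur - min_sep)
    if (!nrow(blinks) ||
        all(bstart > blinks$end + min_sep | bstart + bdur < blinks$start - min_sep)) {
      blinks <- rbind(blinks, data.frame(start = bstart, end = bstart + bdur))
    }
  }
  blinks <- blinks[order(blinks$start), , drop = FALSE]
  rownames(blinks) <- NULL

  # Sample grid
  dt_ms <- 1000 / cfg$sampling_frequency
  n <- round(cfg$duration * cfg$sampling_frequency)
  rel_ms <- (seq_len(n) - 1L) * dt_ms
  base_x <- numeric(n); base_y <- numeric(n)
  for (f in seq_len(nrow(fixations))) {
    idx <- rel_ms >= fixations$start[f] & rel_ms < fixations$end[f]
    base_x[idx] <- fixations$x[f]; base_y[idx] <- fixations$y[f]
  }
  in_fixation <- rep(FALSE, n)
  for (f in seq_len(nrow(fixations))) {
    in_fixation <- in_fixation |
      (rel_ms >= fixations$start[f] & rel_ms < fixations$end[f])
  }
  for (s in seq_len(nrow(saccades))) {
    idx <- which(rel_ms >= saccades$start[s] & rel_ms < saccades$end[s])
    if (!length(idx)) next
    frac <- (rel_ms[idx] - saccades$start[s]) /
      (saccades$end[s] - saccades$start[s])
    base_x[idx] <- saccades$x0[s] + frac * (saccades$x1[s] - saccades$x0[s])
    base_y[idx] <- saccades$y0[s] + frac * (saccades$y1[s] - saccades$y0[s])
  }
  # tail after a truncated timeline: hold last position
  covered <- in_fixation
  for (s in seq_len(nrow(saccades))) {
    covered <- covered | (rel_ms >= saccades$start[s] & rel_ms < saccades$end[s])
  }
  if (any(!covered) && any(covered)) {
    last_pos <- c(base_x[max(which(covered))], base_y[max(which(covered))])
    base_x[!covered] <- last_pos[1]; base_y[!covered] <- last_pos[2]
  }
  in_blink <- rep(FALSE, n)
  for (b in seq_len(nrow(blinks))) {
    in_blink <- in_blink | (rel_ms >= blinks$start[b] & rel_ms <= blinks$end[b])
  }
  pupil <- cfg$pupil_baseline + cfg$pupil_drift_amplitude *
    sin(2 * pi * (rel_ms / 1000) / cfg$pupil_drift_period)

  samples <- list()
  disparity <- c(left = -1, right = 1)   # fixed 2 px horizontal separation
  for (eye in cfg$eyes) {
    noise_x <- ifelse(in_fixation, rnorm(n, 0, cfg$noise_sd), 0)
    noise_y <- ifelse(in_fixation, rnorm(n, 0, cfg$noise_sd), 0)
    x <- base_x + disparity[[eye]] + noise_x
    y <- base_y + noise_y
    p <- pupil
    x[in_blink] <- NA_real_; y[in_blink] <- NA_real_; p[in_blink] <- NA_real_
    samples[[eye]] <- data.frame(time_ms = cfg$start_timestamp + rel_ms,
                                 x = round(x, 1), y = round(y, 1),
                                 pupil = round(p, 1))
  }

  msg_times <- if (cfg$n_trial_messages > 0) {
    seq(0, dur_ms, length.out = cfg$n_trial_messages + 2)[
      seq_len(cfg$n_trial_messages) + 1L]
  } else numeric(0)
  messages <- data.frame(
    time = msg_times / 1000,
    text = if (length(msg_times)) paste("TRIALID", seq_along(msg_times)) else character(0),
    stringsAsFactors = FALSE)

  truth <- list(
    fixations = transform(fixations, start = start / 1000, end = end / 1000),
    saccades = transform(saccades, start = start / 1000, end = end / 1000),
    blinks = transform(blinks, start = start / 1000, end = end / 1000),
    messages = messages)
  list(truth = truth, samples = samples, cfg = cfg)
}

format_ms <- function(ms) {
  # device timestamps: integral ms printed as integers, sub-ms with 1 decimal
  ifelse(ms == round(ms), sprintf("%.0f", ms), sprintf("%.1f", ms))
}

#' Render a simulated session as EyeLink ASC text
#'
#' Emits the header (`SAMPLES ... RATE`, `DISPLAY_COORDS`, `PUPIL`), the
#' monocular or binocular sample block (missing cells as `"."`), `MSG`
#' trigger lines and the `EFIX`/`ESACC`/`EBLINK` event lines implied by the
#' ground truth, in the grammar documented at [parse_asc()]. Parsing the
#' output recovers the sampling frequency, sample counts and per-type event
#' counts exactly.
#'
#' @param sim result of [simulate_session()].
#' @return character vector of ASC lines.
#' @export
render_asc <- function(sim) {
  cfg <- sim$cfg; truth <- sim$truth
  t0 <- cfg$start_timestamp
  eyes <- cfg$eyes
  eye_tokens <- toupper(eyes)
  lines <- c(
    "** CONVERTED FROM SYNTHETIC SESSION",
    sprintf("DISPLAY_COORDS 0 0 %d %d", cfg$screen[1] - 1L, cfg$screen[2] - 1L),
    sprintf("START\t%s \t%s\tSAMPLES\tEVENTS", format_ms(t0),
            paste(eye_tokens, collapse = "\t")),
    "PRESCALER\t1",
    "PUPIL\tAREA",
    sprintf("SAMPLES\tGAZE\t%s\tRATE\t%.2f\tTRACKING\tCR",
            paste(eye_tokens, collapse = "\t"), cfg$sampling_frequency))
  fmt <- function(v) ifelse(is.na(v), ".", sprintf("%.1f", v))
  if (length(eyes) == 2L) {
    L <- sim$samples$left; R <- sim$samples$right
    sample_lines <- paste(format_ms(L$time_ms), fmt(L$x), fmt(L$y),
                          fmt(L$pupil), fmt(R$x), fmt(R$y), fmt(R$pupil),
                          "...", sep = "\t")
  } else {
    S <- sim$samples[[eyes]]
    sample_lines <- paste(format_ms(S$time_ms), fmt(S$x), fmt(S$y),
                          fmt(S$pupil), "...", sep = "\t")
  }
  msg_lines <- if (nrow(truth$messages)) {
    sprintf("MSG\t%s %s", format_ms(t0 + truth$messages$time * 1000),
            truth$messages$text)
  } else character(0)
  # Event timestamps are rounded onto the 0.1 ms grid before printing so the
  # printed duration is exactly (printed end - printed start).
  ev_lines <- character(0)
  r1 <- function(v) round(v, 1)
  for (eye in eyes) {
    tag <- c(left = "L", right = "R")[[eye]]
    fx <- truth$fixations
    if (nrow(fx)) {
      s <- r1(t0 + fx$start * 1000); e <- r1(t0 + fx$end * 1000)
      ev_lines <- c(ev_lines, sprintf(
        "EFIX %s   %s\t%s\t%s\t  %.1f\t  %.1f\t  %.0f", tag,
        format_ms(s), format_ms(e), format_ms(r1(e - s)), fx$x, fx$y,
        rep(cfg$pupil_baseline, nrow(fx))))
    }
    sc <- truth$saccades
    if (nrow(sc)) {
      s <- r1(t0 + sc$start * 1000); e <- r1(t0 + sc$end * 1000)
      ev_lines <- c(ev_lines, sprintf(
        "ESACC %s  %s\t%s\t%s\t  %.1f\t  %.1f\t  %.1f\t  %.1f\t  %.2f\t  %.0f",
        tag, format_ms(s), format_ms(e), format_ms(r1(e - s)),
        sc$x0, sc$y0, sc$x1, sc$y1, sc$amplitude, sc$peak_velocity))
    }
    bl <- truth$blinks
    if (nrow(bl)) {
      s <- r1(t0 + bl$start * 1000); e <- r1(t0 + bl$end * 1000)
      ev_lines <- c(ev_lines, sprintf(
        "EBLINK %s %s\t%s\t%s", tag,
        format_ms(s), format_ms(e), format_ms(r1(e - s))))
    }
  }
  # END carries the last sample's timestamp so the stop event stays inside
  # the recording span.
  n_total <- sum(vapply(sim$samples, nrow, integer(1)))
  last_ms <- if (n_total) {
    max(vapply(sim$samples, function(s) max(c(s$time_ms, -Inf)), numeric(1)))
  } else t0
  end_line <- sprintf("END\t%s \tSAMPLES\tEVENTS", format_ms(last_ms))
  c(lines, sample_lines, msg_lines, ev_lines, end_line)
}

#' Build a ready-made BIDS fixture tree with known ground truth
#'
#' Simulates `n_subjects` sessions (seeds `cfg$seed + 0 .. n-1`), renders
#' each to ASC, converts via [convert_session()], and writes a JSON manifest
#' mapping every produced file set to its ground-truth event counts. The
#' resulting tree passes [validate_dataset()] with zero errors.
#'
#' @param cfg a [sim_config()] template.
#' @param n_subjects number of subjects.
#' @param ctx_template an [acquisition_context()]; its subject label is
#'   replaced by `01`, `02`, ...
#' @param root output directory.
#' @return invisibly, a list with `files` (all paths written) and `truths`
#'   (per-subject ground truth).
#' @export
make_fixture_dataset <- function(cfg, n_subjects, ctx_template, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  files <- character(0); truths <- list(); manifest <- list()
  for (i in seq_len(n_subjects)) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i - 1L
    sim <- simulate_session(cfg_i)
    session <- parse_asc(render_asc(sim))
    sub <- sprintf("%02d", i)
    ctx <- ctx_template; ctx$subject <- sub
    w <- convert_session(session, ctx, root, overwrite = TRUE)
    files <- c(files, w)
    truths[[sub]] <- sim$truth
    manifest[[paste0("sub-", sub)]] <- list(
      seed = cfg_i$seed, eyes = cfg_i$eyes,
      n_fixations = nrow(sim$truth$fixations),
      n_saccades = nrow(sim$truth$saccades),
      n_blinks = nrow(sim$truth$blinks),
      n_messages = nrow(sim$truth$messages),
      files = as.list(basename(w)))
  }
  write_json_sidecar(manifest, file.path(root, "ground_truth_manifest.json"))
  invisible(list(files = files, truths = truths,
                 manifest = file.path(root, "ground_truth_manifest.json")))
}
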