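# Fixture builders shared by the test files. Everything is generated in code
# at test time; no stored binary data.

quick_cfg <- function(seed = 1, duration = 1, sampling_frequency = 500,
                      eyes = c("left", "right"), ...) {
  sim_config(duration = duration, sampling_frequency = sampling_frequency,
             eyes = eyes, seed = seed, ...)
}

# Simulate, render, convert one subject into a fresh BIDS tree; returns
# paths and the ground truth.
make_clean_tree <- function(seed = 1, eyes = c("left", "right"),
                            modality = "func", root = tempfile("bids")) {
  sim <- simulate_session(quick_cfg(seed = seed, eyes = eyes))
  session <- parse_asc(render_asc(sim))
  ctx <- acquisition_context("01", "visualSearch", main_modality = modality,
                             main_modality_start = if (modality == "func")
                               sim$cfg$start_timestamp / 1000 + 2 else NA_real_)
  files <- convert_session(session, ctx, root, overwrite = TRUE)
  list(root = root, files = files, sim = sim, session = session, ctx = ctx)
}

tree_file <- function(tree, pattern) {
  hit <- grep(pattern, tree$files, value = TRUE)
  stopifnot(length(hit) == 1L)
  hit
}

edit_sidecar <- function(path, fn) {
  sc <- etbids:::read_json_sidecar(path)
  etbids:::write_json_sidecar(fn(sc), path)
}

edit_tsvgz <- function(path, fn) {
  lines <- etbids:::read_tsvgz_lines(path)
  etbids:::write_tsvgz(fn(lines), path)
}

# One single-rule mutation per validator rule, each applied to a fresh clean
# binocular tree; used by the validator unit tests and the rule-completeness
# contract.
mutations <- list(
  ET01 = function(tree) {
    # invalid character in an entity value; the matching events pair is
    # removed so the only defect is the name grammar
    tsv <- tree_file(tree, "eye1_physio\\.tsv\\.gz$")
    json <- sub("\\.tsv\\.gz$", ".json", tsv)
    bad_tsv <- file.path(dirname(tsv),
                         "sub-01_task-visualSearch_recording-eye#1_physio.tsv.gz")
    file.rename(tsv, bad_tsv)
    file.rename(json, sub("\\.tsv\\.gz$", ".json", bad_tsv))
    file.remove(tree_file(tree, "eye1_physioevents\\.tsv\\.gz$"))
    file.remove(tree_file(tree, "eye1_physioevents\\.json$"))
  },
  ET02 = function(tree) {
    file.remove(sub("\\.tsv\\.gz$", ".json",
                    tree_file(tree, "eye1_physio\\.tsv\\.gz$")))
  },
  ET03 = function(tree) {
    edit_sidecar(tree_file(tree, "eye1_physio\\.json$"),
                 function(sc) { sc$SamplingFrequency <- NULL; sc })
  },
  ET04 = function(tree) {
    edit_sidecar(tree_file(tree, "eye1_physio\\.json$"),
                 function(sc) { sc$StartTime <- NULL; sc })
  },
  ET05 = function(tree) {
    # drop y_coordinate from both the sidecar and the table
    edit_sidecar(tree_file(tree, "eye1_physio\\.json$"), function(sc) {
      sc$Columns <- sc$Columns[unlist(sc$Columns) != "y_coordinate"]
      sc
    })
    edit_tsvgz(tree_file(tree, "eye1_physio\\.tsv\\.gz$"), function(l) {
      vapply(strsplit(l, "\t"), function(f) paste(f[-3], collapse = "\t"),
             character(1))
    })
  },
  ET06 = function(tree) {
    edit_tsvgz(tree_file(tree, "eye1_physio\\.tsv\\.gz$"), function(l) {
      l[5] <- paste0(l[5], "\t99")
      l
    })
  },
  ET07 = function(tree) {
    edit_sidecar(tree_file(tree, "eye1_physio\\.json$"),
                 function(sc) { sc$RecordedEye <- NULL; sc })
  },
  ET08 = function(tree) {
    # both recording labels claim the same eye
    edit_sidecar(tree_file(tree, "eye2_physio\\.json$"),
                 function(sc) { sc$RecordedEye <- "left"; sc })
  },
  ET09 = function(tree) {
    edit_sidecar(tree_file(tree, "eye1_physioevents\\.json$"),
                 function(sc) { sc$OnsetSource <- "device_time"; sc })
  },
  ET10 = function(tree) {
    edit_tsvgz(tree_file(tree, "eye1_physio\\.tsv\\.gz$"),
               function(l) l[-10])
  },
  ET11 = function(tree) {
    edit_tsvgz(tree_file(tree, "eye1_physioevents\\.tsv\\.gz$"), function(l) {
      f <- strsplit(l[length(l)], "\t")[[1]]
      f[1] <- "999999"
      c(l, paste(f, collapse = "\t"))
    })
  },
  ET12 = function(tree) {
    edit_sidecar(tree_file(tree, "eye1_physio\\.json$"),
                 function(sc) { sc$pupil_size <- NULL; sc })
  },
  ET13 = function(tree) {
    edit_tsvgz(tree_file(tree, "eye1_physio\\.tsv\\.gz$"), function(l) {
      c("timestamp\tx_coordinate\ty_coordinate\tpupil_size", l)
    })
  })

# A hand-written minimal monocular ASC (1000 Hz, left eye, one blink of
# 120 ms), used as a parser oracle independent of the simulator.
hand_asc <- function(n = 1000, t0 = 5000, blink_start = 5100,
                     blink_len = 120) {
  ts <- t0 + seq_len(n) - 1
  in_blink <- ts >= blink_start & ts < blink_start + blink_len
  lines <- c(
    "** hand-built session",
    "DISPLAY_COORDS 0 0 1023 767",
    sprintf("START\t%d \tLEFT\tSAMPLES\tEVENTS", t0),
    "PUPIL\tAREA",
    "SAMPLES\tGAZE\tLEFT\tRATE\t1000.00\tTRACKING\tCR",
    ifelse(in_blink,
           sprintf("%d\t.\t.\t.\t...", ts),
           sprintf("%d\t512.0\t384.0\t1200.0\t...", ts)),
    sprintf("MSG\t%d TRIALID 1", t0 + 10),
    sprintf("EBLINK L %d\t%d\t%d", blink_start, blink_start + blink_len,
            blink_len),
    sprintf("EFIX L   %d\t%d\t%d\t  512.0\t  384.0\t  1200", t0, t0 + n - 1,
            n - 1),
    sprintf("END\t%d \tSAMPLES\tEVENTS", t0 + n - 1))
  lines
}

# Write a physio pair from raw parts, bypassing the typed constructors, so
# validator tests can seed arbitrary violations.
write_raw_physio <- function(dir, columns, rows, sidecar_extra = list(),
                             stem = "sub-01_task-visualSearch_recording-eye1_physio") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, paste0(stem, ".tsv.gz"))
  json <- file.path(dir, paste0(stem, ".json"))
  etbids:::write_tsvgz(rows, tsv)
  sc <- c(list(SamplingFrequency = 1000, StartTime = 0,
               Columns = as.list(columns), PhysioType = "eyetrack",
               RecordedEye = "left", SampleCoordinateSystem = "gaze-on-screen",
               SampleCoordinateUnits = "pixels"),
          sidecar_extra)
  for (nm in setdiff(columns, c("timestamp", "x_coordinate", "y_coordinate"))) {
    if (is.null(sc[[nm]])) sc[[nm]] <- list(Description = nm, Units = "arbitrary")
  }
  etbids:::write_json_sidecar(sc, json)
  c(tsv = tsv, json = json)
}
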