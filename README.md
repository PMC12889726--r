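# etbids

Eye-tracking recordings — gaze position and pupil size over time — are
collected with a zoo of devices and exported in vendor-specific formats,
which makes sharing and reusing them needlessly hard. The Brain Imaging Data
Structure (BIDS) solves this for neuroimaging by prescribing directory
layout, filenames and metadata; its treatment of physiological recordings
extends naturally to eye-tracking. `etbids` implements that eye-tracking
encoding as a working R toolkit for researchers who collect gaze data
alongside fMRI, EEG/MEG or behavioral experiments:

* **parse** the EyeLink ASC plain-text export (samples, `MSG` lines,
  `EFIX`/`ESACC`/`EBLINK` events, monocular or binocular);
* **convert** sessions into compliant `*_physio.tsv.gz` /
  `*_physioevents.tsv.gz` pairs with sidecar JSON metadata, one file set per
  eye (`recording-eye1`, `recording-eye2`);
* **validate** existing BIDS trees against the eye-tracking rule catalogue
  (ET01–ET13), including the metadata unlocked by
  `PhysioType = "eyetrack"`;
* **simulate** realistic synthetic sessions — alternating fixations and
  saccades, blinks, pupil drift, trigger messages — with known ground truth,
  so the whole chain is testable without any real recording.

## The encoding in a nutshell

Filenames are chains of `key-value` entities ending in a suffix, e.g.
`sub-01_task-visualSearch_recording-eye1_physio.tsv.gz`. A physio file is a
gzip-compressed, headerless, tab-separated table of one uniformly sampled
recording; its sidecar JSON must state `SamplingFrequency` (Hz), `StartTime`
(seconds relative to the main acquisition's first sample — negative when the
tracker started earlier) and `Columns`. The table needs at minimum three
columns — `timestamp` first, then `x_coordinate` and `y_coordinate` — with
`pupil_size` optional and further columns allowed as long as the sidecar
describes them. Setting `PhysioType` to the reserved keyword `"eyetrack"`
makes `RecordedEye` (`left`, `right` or `cyclopean`), `SampleCoordinateSystem`
and the `recording` filename entity mandatory, and each physio file may hold
at most one eye. Asynchronous device output — messages, fixations, saccades,
blinks, start/stop marks — goes into a companion `physioevents` table whose
sidecar names, via `OnsetSource`, the recording column whose timescale the
event onsets reference.

## Worked example

```r
library(etbids)

# a 5 s binocular session at 500 Hz, with known ground truth
cfg <- sim_config(duration = 5, sampling_frequency = 500, seed = 42)
sim <- simulate_session(cfg)
asc <- tempfile(fileext = ".asc")
writeLines(render_asc(sim), asc)

session <- read_asc(asc)
session
#> <asc_session> eyes: left+right; rate: 500 Hz; samples: 2500/2500 (L/R); events: 86; messages: 5

ctx <- acquisition_context("01", "visual search", main_modality = "func",
                           main_modality_start = 1002)
root <- tempfile()
files <- convert_session(session, ctx, root)
basename(files)
#> [1] "sub-01_task-visualSearch_recording-eye1_physio.tsv.gz"
#> [2] "sub-01_task-visualSearch_recording-eye1_physio.json"
#> [3] "sub-01_task-visualSearch_recording-eye1_physioevents.tsv.gz"
#> [4] "sub-01_task-visualSearch_recording-eye1_physioevents.json"
#> [5] "sub-01_task-visualSearch_recording-eye2_physio.tsv.gz"
#> [6] "sub-01_task-visualSearch_recording-eye2_physio.json"
#> [7] "sub-01_task-visualSearch_recording-eye2_physioevents.tsv.gz"
#> [8] "sub-01_task-visualSearch_recording-eye2_physioevents.json"
```

The binocular session fans out into two file sets under `sub-01/func/`, one
per eye. The free-text task label was sanitized to the BIDS-safe token
`visualSearch`. The eye-1 sidecar reads:

```json
{
    "SamplingFrequency": 500,
    "StartTime": -2,
    "Columns": ["timestamp", "x_coordinate", "y_coordinate", "pupil_size"],
    "PhysioType": "eyetrack",
    "RecordedEye": "left",
    "SampleCoordinateSystem": "gaze-on-screen",
    "SampleCoordinateUnits": "pixels",
    ...
}
```

`StartTime` is −2 s because the simulated tracker started two seconds before
the (here, fMRI) acquisition at device time 1002 s. Validation of the
produced tree is clean, and `cmd_inspect()` summarizes the raw file:

```r
nrow(validate_dataset(root))
#> [1] 0
cmd_inspect(asc)
#> eyes: left, right; rate: 500 Hz
#> duration: 4.998 s; samples: 2500 (left) / 2500 (right)
#> left events: 21 fixations, 20 saccades, 2 blinks
#> right events: 21 fixations, 20 saccades, 2 blinks
#> messages: 5; unknown lines: 0
```

The reported event counts equal the simulator's ground truth — the
conversion is lossless for counts, and sample values survive to the written
TSV exactly (shortest round-trip decimal rendering).

A shell entry point wrapping the same functions is installed with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "etbids", package = "etbids"))') \
  convert recording.asc --bids-root out --sub 01 --task visualSearch --modality func
```

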