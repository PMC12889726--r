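---
title: "Encoding, validating and simulating eye-tracking recordings in BIDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding, validating and simulating eye-tracking recordings in BIDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etbids)
```

## The problem and the model

Video-based eye-trackers report, at a fixed sampling rate, where a person is
looking on a screen and how large their pupil is. Two properties make these
data awkward for generic tabular standards. First, a recording is a
*continuous, uniformly sampled* stream in which data loss (most prominently
blinks, when the eyelid occludes the pupil) must be represented as missing
samples rather than deleted rows, or the time axis breaks. Second, the
device emits *asynchronous* output interleaved with the stream: free-text
messages, calibration reports, experiment triggers, and model-derived events
such as fixations, saccades and blinks, each a single timestamped line
rather than a sample.

`etbids` encodes both under the Brain Imaging Data Structure. The continuous
stream becomes a headerless, gzip-compressed TSV (`*_physio.tsv.gz`) whose
sidecar JSON carries the information needed to reconstruct the timeframe:
`SamplingFrequency` in Hz, `StartTime` in seconds relative to the first
sample of the main acquisition (negative when the tracker started earlier —
the usual case, since trackers are typically armed before a scanner), and
the ordered `Columns` list, which is the sole authority on column identity
because the data file has no header. The asynchronous output becomes a
companion `*_physioevents.tsv.gz` table; its sidecar's `OnsetSource` field
names the recording column (here always `timestamp`) on whose timescale the
event onsets live, which is what ties the two files together.

Setting the sidecar field `PhysioType` to the reserved keyword `"eyetrack"`
switches on the eye-tracking contract: `RecordedEye` (one of `left`,
`right`, `cyclopean`), `SampleCoordinateSystem`, and the `recording`
filename entity become mandatory, and each physio file may contain at most
one eye. A binocular session therefore fans out into two complete file sets,
`recording-eye1` (left) and `recording-eye2` (right).

## Parsing the device export

The EyeLink ASC dialect is a line-oriented mix of numeric sample rows,
`MSG` lines, event lines and header/control lines. The format has no
normative grammar, so the parser documents the de-facto layout it accepts
(see `?parse_asc`): monocular samples are
`<ts> <x> <y> [<pupil>] [flags]`, binocular samples carry the left triplet
then the right, the missing-data marker is `"."`, and end-of-event lines are

```
EFIX  <L|R> <start> <end> <dur> <x> <y> <pupil>
ESACC <L|R> <start> <end> <dur> <x0> <y0> <x1> <y1> <amp> <pv>
EBLINK <L|R> <start> <end> <dur>
```

Start-of-event lines (`SFIX`, `SSACC`, `SBLINK`) are ignored because their
end-of-event counterparts carry complete information. The parser is
deliberately permissive — unknown lines are counted, never fatal —
because strictness belongs in the validator, which sees the *converted*
dataset. Two conditions do abort a parse: a file with zero classifiable
lines is not an ASC file at all, and an inconsistent field count inside the
sample block means the monocular/binocular layout cannot be trusted.

Device timestamps are integer or fractional milliseconds. They are converted
to seconds by dividing each value by 1000 individually — never by
accumulating floating-point increments — so millisecond precision survives
exactly, and the physio `timestamp` column keeps *device* time. Keeping
device time (rather than re-zeroing) is what lets physioevents onsets
reference the same clock via `OnsetSource`, with `StartTime` carrying the
alignment to the main modality separately. If the `SAMPLES` header lacks a
`RATE` field, the rate is inferred from the modal sample spacing with a
warning.

## Validation rules and numerical choices

The validator applies a catalogue of thirteen rules (ET01–ET13; the full
list is in `?validate_physio_pair` and the source header). Statements the
encoding treats as MUST-level surface as errors; RECOMMENDED-level
statements — indexed recording labels such as `eye1`, manufacturer metadata
— surface as warnings. Notable operationalizations:

* **Uniform sampling (ET10).** The standard demands uniform sampling but
  states no tolerance. We flag any consecutive timestamp difference whose
  deviation from `1/SamplingFrequency` exceeds 1% of the sample period.
  The margin absorbs decimal-text rounding of timestamps while still
  catching the smallest real defect, a single dropped sample (a gap of
  twice the period).
* **Single eye (ET08).** "At most one eye per file" needs a checkable form:
  a physio table may not declare two x- or y-coordinate-like columns, and
  two files within one acquisition may not declare the same `RecordedEye`
  under different recording labels.
* **Events outside the recording span (ET11).** Devices legitimately log
  messages before the first and after the last sample, so this is a
  warning, not an error.
* **Column description (ET12).** Every column beyond the mandatory trio
  (`timestamp`, `x_coordinate`, `y_coordinate`) must be described by a
  sidecar metadata object. `pupil_size` is deliberately included: it is
  optional to *have*, but once present its meaning (area vs diameter,
  units) is device-dependent and must be stated.

All violations in a file are reported, not just the first, and issue lists
are deterministically ordered (path, then rule), which makes the validator
usable as a converter-debugging tool and makes runs reproducible.

Serialization choices are fixed so that output is byte-reproducible:
missing cells are written as `n/a` (the BIDS-wide convention), numbers use
the shortest decimal text that round-trips to the same double, JSON sidecars
use a canonical key order (the timeframe fields first, the rest
alphabetical) with 4-space indent, and the gzip stream carries no
modification time. Byte determinism is not cosmetic — it makes converted
datasets diffable and lets tests assert reproducibility exactly.

## What the simulator models — and what it does not

The synthetic-session generator exists so every stage is testable with known
ground truth. It draws an alternating fixation/saccade scanpath: fixation
durations from a Gamma distribution (default shape 7, scale 30 ms, i.e.
~210 ms mean — a plausible magnitude for scene viewing, not a fit to any
dataset), fixation targets uniform on the screen, saccade durations from the
conventional main-sequence approximation `2.2 × amplitude(deg) + 21` ms with
a configurable pixels-per-degree factor, and linear interpolation along the
saccade path. When a drawn saccade would overrun the session, the final
fixation is extended to the session end, so fixations and saccades tile the
timeline exactly. Blinks arrive as a Poisson count (default 15 per minute)
with uniform durations of 100–300 ms, placed without overlap and separated
by at least three sample periods so each blink is one distinct missing-data
gap; during a blink, gaze and pupil are missing. Pupil size is a baseline
plus a slow sinusoid (default period 20 s); positional noise (default SD
0.5 px) is added during fixations only. Both eyes share the scanpath, with a
fixed 2 px horizontal disparity and independent noise. All defaults are
package choices of plausible magnitude and are documented as such — they are
not measurements from any particular device or study.

What the simulator does **not** model bounds what passing tests demonstrate:
no microsaccades, drift or post-saccadic oscillations; no smooth pursuit; no
saliency-driven gaze; no tracker-specific artifacts (corneal-reflection
loss, partial occlusion, velocity-based event misdetection). Tests built on
it therefore demonstrate that the encoding, conversion and validation chain
is correct and lossless — not that any scientific analysis of real gaze data
would behave well. Calibration quality, for instance, is passed through as
verbatim device messages, never recomputed.

Each session uses a single pseudo-random stream keyed by its seed, and the
generator restores the caller's RNG state on exit, so fixtures are
reproducible and tests cannot interfere with each other through global
state.

## Design choices where the design was open

* **Entity ordering** is fixed as `sub < ses < task < acq < run <
  recording`, with unknown entities preserved after known ones in input
  order: rendering is deterministic and parse∘format is the identity.
* **`.tsv.gz` is one atomic extension token** (matched longest-first), so
  suffix extraction is unambiguous.
* **Eye-to-index mapping** is fixed: left→`eye1`, right→`eye2`,
  cyclopean→`eye3`. Indexed labels are only recommended by the encoding, so
  non-indexed labels warn rather than fail.
* **Cyclopean streams** are produced only on explicit request by averaging
  both eyes at conversion time; raw files are never assumed to contain one.
* **Task labels** are sanitized to camelCase alphanumeric tokens
  (`"visual search"` → `"visualSearch"`), since entity values must be
  strictly alphanumeric.
* **The physioevents column vocabulary** (`onset`, `duration`,
  `event_type`, `eye`, `message`, then sorted parameter columns) is a
  documented package choice isolated inside the serializer, so it can track
  the released schema vocabulary without touching callers.
* **The command-line surface** is a set of exported functions
  (`cmd_convert`, `cmd_validate`, `cmd_simulate`, `cmd_inspect`,
  dispatched by `etbids_run`) plus a thin Rscript wrapper in
  `inst/scripts/etbids`; exit codes are stable (0 success, 2 parse,
  3 write, 4 validation) and logs go to standard error so reports can be
  piped cleanly.

## Problem sizes used in the tests

The test suite and the reproduction script run entirely on simulated
sessions of 1–5 s at 250–1000 Hz (500–5000 samples per eye), with 20 seeds
for the converter–validator closure property and a 13-mutation corpus (one
seeded violation per rule) for validator completeness. These sizes exercise
every code path — binocular splitting, blink gaps, truncated headers,
empty event tables — while keeping the suite fast; nothing in the
implementation depends on recording length, and the streaming-free design
(whole files in memory) is appropriate for the minutes-long sessions typical
of task-based experiments.

## Known limitations

Only the EyeLink ASC dialect is read; binary EDF and other vendors' formats
(Tobii, Pupil Labs, webcam trackers) are out of scope — export to ASC
first. Sidecar inheritance across directory levels is not resolved; each
pair is validated standalone. The validator covers the eye-tracking subset
only, not the full general-BIDS schema (NIfTI headers, task `events.tsv`,
participant metadata). Gaze analysis beyond reading device-reported events
(e.g. velocity-based saccade re-detection) is deliberately not provided.
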