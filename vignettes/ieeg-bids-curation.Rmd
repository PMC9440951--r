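---
title: "Curating clinical iEEG into BIDS: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating clinical iEEG into BIDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegcurate)
```

## The problem

Epilepsy-surgery centers accumulate two kinds of intracranial EEG.
Intraoperative ECoG is recorded in the operating room in a sequence of
*situations*: the surgeon places a grid or strips, a recording is made, the
configuration changes or tissue is resected, and another recording follows,
until a final post-resection check. Long-term ECoG/SEEG comes from days of
invasive monitoring between electrode implantation and a later resection.
Both arrive as proprietary binary files (a Micromed-style TRC dialect here)
whose headers carry patient identity and whose scientific metadata —
electrode layout, channel quality, sleep and seizure periods, stimulation
protocols — exists only as free-text annotations made by clinicians.

`ieegcurate` converts this material into iEEG-BIDS while preserving
clinical meaning: which contacts sat on tissue that was later removed,
which channels were unusable and why, when seizures happened, and how each
recording relates in time to the implantation.

## The TRC dialect and its guarantees

The codec models the fields a conversion needs — patient area, acquisition
start, per-channel scaling, in-file notes — at fixed documented offsets,
and carries everything else as one opaque byte block. Two contracts matter
downstream:

* **Scaling.** A raw 16-bit sample maps to physical units as
  `phys = (raw − logic_ground) / (logic_max − logic_min + 1) × (phys_max − phys_min)`.
  The default table spans the full unsigned 16-bit range with mid-range
  ground and ±3276.8 µV, i.e. a least significant bit of 0.1 µV. The
  quantizer guarantees `|phys(raw(x)) − x| ≤ 1 LSB` for in-range `x`, and
  clipping is an error, never silent saturation.
* **Round trip.** Writing is deterministic (notes stored in ascending
  sample order, stable for ties) and `read_trc(write_trc(r))` restores
  every modeled field and the opaque block, so write → read → write is
  byte-identical. The test suite exercises this over 100 seeded synthetic
  recordings.

One sampling rate per file is enforced; the supported set
{256, 512, 1024, 2048} Hz reflects the acquisition hardware this dialect
emulates. Note text is capped at 40 characters (the field width); longer
statements are split by the annotator into continuation notes that begin
with `";"` at the same sample index, and `parse_annotations()` rejoins
them. This continuation rule is this package's own convention, needed
because the canonical two-grid/two-strip layout string is 43 characters.

## The annotation grammar

Every note is classified by its leading token; classification is *total* —
free-text surgeon comments are kept verbatim as `unparsed`, never an error,
and every note lands in exactly one category.

* `Format;` / `ECoG;` / `SEEG;` declare the electrode layout as
  `Name[R×C]` groups. Bare keywords `grid`, `strip`, `depth` switch the
  electrode type for subsequent groups; the default is grid after
  `Format;`/`ECoG;` and depth after `SEEG;`. Strips and depth electrodes
  are one-dimensional by construction (`rows = 1`). Both `×` and `x` are
  accepted; the canonical serialization uses `x`, no spaces, and inserts a
  type keyword only where the type changes, so
  `parse_format(canonical_format_string(s))` is the identity.
* `Bad;`, `Silicon;`, `Screw;` mark channels, mapping to BIDS
  `status = "bad"` with status descriptions "noisy after visual
  inspection", "electrode on top of other electrode" and "located in
  screw" respectively.
* `Sl_on`/`Sl_off` and friends bracket events. Pairing is per
  (code, channel set): different codes interleave freely, the same code may
  not nest, an unmatched `_off` is an error (it indicates a corrupted
  annotation stream), and an unmatched `_on` closes at the end of the
  recording with a warning. The built-in vocabulary (Sl, Sz, Art, Good,
  Rest, SPES, Mtr, Lang, SSEP) is extensible via `extra_codes`, since
  centers add protocols over time.
* `Task;label` declares the task explicitly. Without it, the task is
  inferred from the segment code with the largest sample coverage among
  those with a task mapping (sleep, SPESclin, motor, language, SSEP,
  seizure), defaulting to `rest` — a recording dominated by a sleep period
  is a sleep task even if a short artefact is also marked.

## Resection labels

The clinically central quantity is, per contact, whether it recorded from
tissue that was later resected. A contact is a disc of radius `r`
(default 2 mm, a typical exposed clinical contact; configurable). With `d`
the signed distance from the contact center to the resection boundary
(negative inside):

* `resected` ⇔ `d < r` — the disc overlaps the resection interior or
  boundary ("completely or partly on top");
* `edge` ⇔ `−r < d < r` (partly on top, i.e. exactly on the edge) **or**
  `r ≤ d` and `d − r ≤ 5` mm — the disc lies within half a centimeter
  outside the boundary;
* `cavity` ⇔ the center lies over a resection cavity from an earlier
  surgery. Such a contact records no brain signal, so cavity suppresses
  the other two labels.

Two choices here were genuinely open and are fixed as follows: the 5 mm
band is measured from the **disc boundary** (`d − r`), consistent with the
contact-area phrasing of the resected rule, and the threshold is
**inclusive** (a gap of exactly 5 mm is edge). Consequences: a contact
straddling the boundary is both resected and edge, which is why
`electrodes.tsv` carries three independent yes/no columns rather than one
fused label; and moving a contact inward along the normal can only gain,
never lose, the resected label (a tested monotonicity property).

In 2D, distances are exact point-to-segment computations against the
photo-plane polygon, with interiority by the even-odd rule; the tests check
agreement with an independent dense-boundary-sampling oracle to within
0.01 mm on 1000 random points. Photo coordinates are calibrated to mm via
the known inter-contact pitch (default 10 mm), using the median of the
measured adjacent-contact pixel distances for robustness.

In 3D, the boundary is voxelized (mask voxels with at least one
6-neighbour outside) and the distance is to the nearest boundary-voxel
center, signed by mask membership of the query point's nearest voxel. This
is exact up to voxelization — about one voxel diagonal — which is the
stated tolerance; an extruded-polygon mask reproduces the 2D labels in its
mid-plane within that tolerance. Since only electrode positions are
queried (tens of points), brute-force distances to the boundary set are
cheaper and simpler than a full distance transform.

## Pseudo-anonymization

`pseudo_anonymize()` rewrites the patient area: surname ← `RESP####`,
given name cleared, birth date truncated to January 1 of the birth year
(the year is kept so age can still be computed). Free-text fields and
notes are scrubbed of denylist tokens by case-insensitive **whole-token**
matching — token boundaries are non-alphanumeric characters — so a montage
called `Jansen-avg` loses the name but a channel label that merely
contains a name substring is untouched. Sample data are never modified.
`verify_scrubbed()` re-scans everything and the composition
`verify ∘ scrub = clean` is a tested invariant.

The recording date is deliberately kept inside the TRC: long-term run
labels need true day arithmetic. Identity-relevant dates only ever reach
the BIDS tree *shifted*: the implantation (or surgery) date maps to
1900-01-01 and all acquisition times preserve their day/time deltas. The
registry TSV linking hospital identifiers to study codes is the only
re-identification key and lives outside any dataset root.

## BIDS assembly

Entity conventions: intraoperative sessions are `ses-SITUATION<n><L>`
with tasks in {acute, SSEP, stimulation} and no run entity (one run per
task per situation); long-term sessions are `ses-1`, `ses-1a`, … with
tasks in {rest, sleep, SPESclin, motor, language, SSEP, seizure} and a
mandatory `run-DDHHMM` label. `DD` = days since implantation + 1, capped
at 99 — monitoring lasts days, not months, so a larger value indicates a
wrong implantation date.

Signals are exported as BrainVision triplets: multiplexed signed 16-bit
binary with per-channel resolution `max(|phys range|)/32767`, which keeps
the read-back error within one least significant bit (tested); the `.vmrk`
holds a single New Segment marker with the shifted start time, and events
live only in `events.tsv` — one source of truth. Intraoperative
`electrodes.tsv` coordinates are written as zeros (positions are defined
by the situation photo named in `coordsystem.json`, where contact
numbering matches electrode names); long-term sessions carry mm
coordinates in patient-specific space. The `size` column is the disc area
`πr²` in mm². `scans.tsv` rows carry the shifted acquisition time plus
per-category event counts, documented in `scans.json`.

`assemble_run()` is idempotent: rebuilding with identical inputs rewrites
identical bytes; the same entity tuple with different content is an
*entity collision* error rather than a silent overwrite. Session-level
files are shared across runs and guarded the same way, which also catches
inconsistent electrode tables between runs of one session.

## The synthetic demonstration study

`generate_demo_study()` emulates a two-arm cohort: by default 6
intraoperative subjects (2–9 situations each, at least one pre-resection
stage and exactly one post-resection stage, a 4 × 5 grid at 10 mm pitch,
a jittered quadrilateral resection outline, occasionally an old-surgery
cavity) and 3 + 3 long-term ECoG/SEEG subjects (one session, runs on two
monitoring days, each with sleep and seizure events; a
two-grid/two-strip or four-depth layout; a spherical 3D resection mask on
a 2 mm grid). Signal content is a sum of low-frequency sinusoids with
Gaussian noise, stereotyped interictal-spike transients, and optional
1 s on/1 s off burst-suppression alternation as seen under propofol —
visually meaningful, but *cosmetic*: no claim of spectral or clinical
realism is made, and passing tests say nothing about real-data artifact
structure, electrode localization error, or the full annotation dialect of
any particular center. What the synthetic arm does establish is
structural correctness: naming, sidecar consistency, label geometry,
anonymization and byte-level determinism (trees are byte-identical for a
fixed seed; registry timestamps are fixed constants for that reason).

Problem sizes are deliberately small — intraoperative fixtures of 20
channels × 4 s at 512 Hz and long-term fixtures of 24–64 channels × 6 s —
because every tested property (round trips, counts, geometry, idempotence)
is independent of recording length.

## Validation

`validate_dataset()` is a structural checker with stable error codes
(`SIDECAR_MISSING`, `RUN_LABEL_FORMAT`, `CHANNEL_COUNT_MISMATCH`,
`EVENT_BOUNDS`, `INTRAOP_NONZERO_COORD`, `SESSION_COUNT`, …): filename
entities, required files per run, channel-count agreement between
`.vhdr`, `channels.tsv` and `_ieeg.json`, event bounds against
`RecordingDuration`, the electrodes column contract, cavity precedence,
the zero-coordinate convention, status/description pairing and
participants session counts. It is intentionally not a replacement for
the official BIDS validator — it checks this package's contracts, which
include center-specific conventions (run-label format, label columns) the
generic validator knows nothing about.

## Known limitations

* The TRC dialect is a documented emulation in the header-type-4 lineage,
  not a byte-level clone of any vendor release; real files from other
  header versions are rejected with a clear error rather than misread.
* Photo-to-mm calibration assumes a measured adjacent-contact pixel
  distance; lens distortion and perspective are out of scope (outlines are
  expected to be drawn in an already-rectified photo plane).
* 3D labeling accuracy is voxel-limited; masks finer than the electrode
  radius are advisable.
* Image registration, brain-shift correction, cortical segmentation and
  atlas assignment are out of scope; coordinates and masks are taken as
  given.
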