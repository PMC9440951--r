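# ieegcurate

Clinical intracranial EEG (iEEG) recorded around epilepsy surgery —
intraoperative electrocorticography (ECoG) on the exposed cortex, and
long-term ECoG/stereo-EEG (SEEG) from days of invasive monitoring — arrives
as proprietary binary files full of patient identity, free-text annotations
and center-specific conventions. `ieegcurate` turns such data into
[BIDS](https://bids-specification.readthedocs.io/) (the iEEG extension),
the layout most analysis tools expect, while keeping every clinically
meaningful piece of metadata machine-readable.

The package is aimed at epilepsy-surgery centers and at researchers who
need realistic, fully synthetic iEEG-BIDS datasets for testing pipelines.

## What it implements

The workflow is six steps, each backed by exported functions:

1. **Subject labels** — an append-only registry maps hospital identifiers to
   `RESP####` study codes (`allocate_resp_id()`), kept in a restricted TSV
   outside any dataset.
2. **Sessions, tasks, runs** — intraoperative recordings map one surgical
   *situation* to one session (`ses-SITUATION1A`: stage number × electrode
   configuration letter; the highest stage is the post-resection recording).
   Long-term recordings use one session per monitoring period and a
   `run-DDHHMM` label, where `DD` is the day after implantation
   (implantation day = 01) and `HHMM` the start time — `run-021315` starts
   at 13:15 on monitoring day 1 (`longterm_run_label()`).
3. **Pseudo-anonymization** — `pseudo_anonymize()` replaces the surname
   with the study code, clears the given name, truncates the birth date to
   January 1 of the birth year, and scrubs name tokens from montages and
   notes; `verify_scrubbed()` proves the result clean.
4. **Resection labels** — each electrode contact (a disc of radius *r*,
   default 2 mm) is classified against the resection geometry. With *d* the
   signed distance of the contact center to the resection boundary
   (negative inside):
   - *resected* ⇔ *d* < *r* (the disc overlaps resected tissue),
   - *edge* ⇔ −*r* < *d* < *r*, or the outside gap *d* − *r* ≤ 5 mm
     (inclusive),
   - *cavity* ⇔ the center lies over a cavity from an earlier surgery
     (recording no brain signal; suppresses the other labels).
   The same thresholds run in 2D photo-plane coordinates
   (`classify_2d()`, polygons drawn on operating-room photos) and in 3D
   against voxel masks (`classify_3d()`).
5. **Annotation grammar** — in-file notes carry the metadata:
   `Format;Gr[4x5]` declares a 4 × 5 grid (20 contacts), `Bad;`/`Silicon;`/
   `Screw;` mark channel status, `Sl_on` … `Sl_off` bracket events
   (sleep, seizure, artefact, stimulation, …), `Task;` declares the task.
   Parsing is total: unknown text is preserved, never an error.
6. **BIDS assembly** — `assemble_run()` writes BrainVision signal triplets
   (`.vhdr`/`.eeg`/`.vmrk`, 16-bit, round-trip faithful to one least
   significant bit), `channels.tsv`, `events.tsv`, `electrodes.tsv` with
   `resected`/`edge`/`cavity` columns, `coordsystem.json`, `_ieeg.json`,
   `scans.tsv` and `participants.tsv`, plus a `sourcedata/` mirror. All
   public dates are shifted so the implantation/surgery day is 1900-01-01.

A Micromed-style TRC binary codec (`read_trc()`/`write_trc()`/
`synthesize_recording()`), a structural validator (`validate_dataset()`)
and a synthetic two-arm demonstration study generator
(`generate_demo_study()`) complete the toolkit.

## Worked example

```r
library(ieegcurate)

fmt <- parse_format("ECoG;C[4 x 8];CH[2 x 8];strip;IHa[1 x 8];IHv[1 x 8]")
contact_count(fmt)
#> [1] 64
canonical_format_string(fmt)
#> [1] "ECoG;C[4x8];CH[2x8];strip;IHa[1x8];IHv[1x8]"

longterm_run_label(as.Date("2010-03-04"),
                   as.POSIXct("2010-03-05 13:15:00", tz = "UTC"))
#> [1] "021315"

plan <- electrode_plan(c("Gr01", "Gr02", "Gr03"),
                       x = c(5, 16, 18), y = c(5, 5, 5))
resection <- resection_outline(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
classify_2d(plan, resection)
#>   label resected  edge cavity
#> 1  Gr01     TRUE FALSE  FALSE
#> 2  Gr02    FALSE  TRUE  FALSE
#> 3  Gr03    FALSE FALSE  FALSE
```

The format string declares a 32-contact grid, a 16-contact grid and two
8-contact strips, 64 contacts in total. `Gr01` sits 5 mm inside the resection
(resected), `Gr02`'s disc boundary is 4 mm outside it (within the 5 mm edge
band), `Gr03`'s gap is 6 mm (outside the band).

A complete synthetic study — two BIDS roots, twelve subjects, recordings,
annotations, resection geometry, validation — comes from:

```r
res <- generate_demo_study(demo_study_spec(6, 3, 3, seed = 1), "demo")
validate_dataset(res$acute_root)$passed
#> [1] TRUE
```

A command-line front end lives at `inst/cli/curate.R`
(`anonymize`, `parse-notes`, `validate`, `demo`).

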