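make_parsed <- function(rec) parse_annotations(rec$notes, n_samples(rec))

intraop_rec <- function(seed = 1, duration_s = 1) {
  notes <- rbind(trc_note(0L, "Format;Gr[4 x 5]"),
                 trc_note(0L, "Bad;Gr07"),
                 trc_note(64L, "Good_on"),
                 trc_note(192L, "Good_off"))
  spec <- signal_spec(sprintf("Gr%02d", 1:20), rate = 256L,
                      duration_s = duration_s, notes = notes,
                      patient = patient_header("RESP0384", "", 1, 1, 1985),
                      recording_start = as.POSIXct("2011-05-10 09:30:00",
                                                   tz = "UTC"))
  synthesize_recording(spec, seed)
}

test_that("intraoperative entities encode the situation scheme", {
  e <- intraop_entities("RESP0384", 1, "A", "acute")
  expect_equal(e$ses, "SITUATION1A")
  expect_equal(e$task, "acute")
  expect_null(e$run)
  expect_equal(intraop_entities("RESP0384", 3, "A", "acute")$ses, "SITUATION3A")
  expect_error(intraop_entities("RESP0384", 1, "1", "acute"), "A-Z")
  expect_error(intraop_entities("RESP0384", 1, "A", "rest"), "task")
})

test_that("long-term run labels encode day-after-implantation and start time", {
  expect_equal(longterm_run_label(as.Date("2010-03-04"),
                                  as.POSIXct("2010-03-05 13:15:00", tz = "UTC")),
               "021315")
  expect_equal(longterm_run_label(as.Date("2010-03-04"),
                                  as.POSIXct("2010-03-04 09:00:00", tz = "UTC")),
               "010900")
  expect_error(longterm_run_label(as.Date("2010-03-04"),
                                  as.POSIXct("2010-03-03 09:00:00", tz = "UTC")),
               "before the implantation")
  expect_error(longterm_run_label(as.Date("2010-03-04"),
                                  as.POSIXct("2010-07-20 09:00:00", tz = "UTC")),
               "2-digit")
  expect_error(longterm_entities("RESP0001", "1", "rest", "21315"), "6-digit")
})

test_that("acquisition times shift onto the 1900 calendar preserving deltas", {
  expect_equal(shift_acq_time(as.POSIXct("2010-03-05 13:15:00", tz = "UTC"),
                              as.Date("2010-03-04")),
               "1900-01-02T13:15:00")
  expect_equal(shift_acq_time(as.POSIXct("2010-03-04 09:00:30", tz = "UTC"),
                              as.Date("2010-03-04")),
               "1900-01-01T09:00:30")
})

test_that("channel status marks map to BIDS status/status_description", {
  rec <- intraop_rec()
  parsed <- make_parsed(rec)
  groups <- parsed$format
  ch <- build_channels(rec, parsed, groups)
  expect_equal(nrow(ch), 20L)
  expect_equal(ch$status[ch$name == "Gr07"], "bad")
  expect_equal(ch$status_description[ch$name == "Gr07"],
               "noisy after visual inspection")
  expect_true(all(ch$status[ch$name != "Gr07"] == "good"))
  expect_true(all(ch$status_description[ch$name != "Gr07"] == "n/a"))
  expect_true(all(ch$type == "ECOG"))

  # screw/silicon marks and depth typing
  notes <- rbind(trc_note(0L, "SEEG;Am[1x4]"), trc_note(0L, "Screw;Am04"),
                 trc_note(0L, "Silicon;Am01"))
  spec <- signal_spec(sprintf("Am%02d", 1:4), rate = 256L, duration_s = 0.5,
                      notes = notes)
  rec2 <- synthesize_recording(spec, 2)
  parsed2 <- make_parsed(rec2)
  ch2 <- build_channels(rec2, parsed2, parsed2$format)
  expect_true(all(ch2$type == "SEEG"))
  expect_equal(ch2$status_description[ch2$name == "Am04"], "located in screw")
  expect_equal(ch2$status_description[ch2$name == "Am01"],
               "electrode on top of other electrode")

  parsed2$statuses$channel[1] <- "Zz99"
  expect_error(build_channels(rec2, parsed2, parsed2$format), "Zz99")
})

test_that("events convert samples to seconds and sort deterministically", {
  segs <- data.frame(code = c("Sz", "Sl"),
                     onset_sample = c(4000L, 1000L),
                     offset_sample = c(4512L, 3048L),
                     channels = c("C05;C06", ""), stringsAsFactors = FALSE)
  ev <- build_events(segs, 512)
  expect_equal(ev$onset, c(1000, 4000) / 512)
  expect_equal(ev$onset[1], 1.953125)
  expect_equal(ev$duration[1], 4.0)
  expect_equal(ev$trial_type, c("sleep", "seizure"))
  expect_equal(ev$channels, c("n/a", "C05;C06"))
  expect_equal(nrow(build_events(segs[0, ], 512)), 0L)
})

test_that("the _ieeg.json sidecar is consistent with the channel table", {
  rec <- intraop_rec()
  parsed <- make_parsed(rec)
  ch <- build_channels(rec, parsed, parsed$format)
  e <- intraop_entities("RESP0384", 1, "A", "acute")
  js <- build_ieeg_json(rec, parsed, e, ch)
  expect_equal(js$SamplingFrequency, 256L)
  expect_equal(js$ECOGChannelCount, 20L)
  expect_equal(js$SEEGChannelCount, 0L)
  expect_equal(js$PowerLineFrequency, 50)
  expect_equal(js$iEEGElectrodeGroups, "Format;Gr[4x5]")
  expect_equal(js$RecordingDuration, 1)
  parsed$format <- NULL
  expect_error(build_ieeg_json(rec, parsed, e, ch), "format")
})

test_that("BrainVision export is deterministic, sized and 1-LSB faithful", {
  rec <- make_rec(seed = 6, n_ch = 2, rate = 256L, duration_s = 0.5)
  base1 <- file.path(withr::local_tempdir(), "out")
  base2 <- file.path(withr::local_tempdir(), "out")
  write_brainvision(rec, base1)
  write_brainvision(rec, base2)
  expect_equal(file.info(paste0(base1, ".eeg"))$size, 2 * 128 * 2)
  expect_identical(file_bytes(paste0(base1, ".eeg")),
                   file_bytes(paste0(base2, ".eeg")))
  expect_identical(readLines(paste0(base1, ".vmrk")),
                   readLines(paste0(base2, ".vmrk")))

  back <- read_brainvision(paste0(base1, ".vhdr"))
  expect_equal(back$labels, rec$channels$label)
  expect_equal(back$sampling_rate, 256)
  err <- abs(back$phys - trc_physical(rec))
  expect_true(all(err <= back$resolution + 1e-12))
})

test_that("assembled intraoperative runs follow the zero-coordinate convention", {
  root <- withr::local_tempdir()
  rec <- intraop_rec()
  parsed <- make_parsed(rec)
  plan <- grid_plan_4x5()
  labels <- classify_2d(plan, unit_square_mm())
  e <- intraop_entities("RESP0384", 1, "A", "acute")
  assemble_run(rec, parsed, labels, e, root,
               reference_date = as.Date("2011-05-10"),
               subject_info = list(sex = "f", age = 26),
               photo = "RESP0384_ses-SITUATION1A_photo.jpg")

  ieeg_dir <- file.path(root, "sub-RESP0384", "ses-SITUATION1A", "ieeg")
  et <- read.delim(file.path(ieeg_dir,
                             "sub-RESP0384_ses-SITUATION1A_electrodes.tsv"))
  expect_true(all(et$x == 0 & et$y == 0 & et$z == 0))
  expect_equal(et$size[1], pi * 4, tolerance = 0.01)
  expect_true(all(c("resected", "edge", "cavity") %in% names(et)))

  cs <- jsonlite::read_json(
    file.path(ieeg_dir, "sub-RESP0384_ses-SITUATION1A_coordsystem.json"))
  expect_equal(cs$IntendedFor, "RESP0384_ses-SITUATION1A_photo.jpg")

  pt <- read.delim(file.path(root, "participants.tsv"))
  expect_equal(pt$participant_id, "sub-RESP0384")
  expect_equal(pt$number_of_sessions, 1L)
})

test_that("nine situations yield nine session directories", {
  root <- withr::local_tempdir()
  rec0 <- intraop_rec()
  parsed <- make_parsed(rec0)
  labels <- classify_2d(grid_plan_4x5(), unit_square_mm())
  sits <- list(c(1, "A"), c(1, "B"), c(1, "C"), c(1, "D"),
               c(2, "A"), c(2, "B"), c(2, "C"), c(2, "D"), c(3, "A"))
  for (s in sits) {
    e <- intraop_entities("RESP0384", as.integer(s[1]), s[2], "acute")
    assemble_run(rec0, parsed, labels, e, root,
                 reference_date = as.Date("2011-05-10"))
  }
  ses <- list.dirs(file.path(root, "sub-RESP0384"), recursive = FALSE)
  expect_length(ses, 9L)
  pt <- read.delim(file.path(root, "participants.tsv"))
  expect_equal(pt$number_of_sessions, 9L)
})

test_that("re-assembly is byte-idempotent and collisions are errors", {
  root <- withr::local_tempdir()
  rec <- intraop_rec()
  parsed <- make_parsed(rec)
  labels <- classify_2d(grid_plan_4x5(), unit_square_mm())
  e <- intraop_entities("RESP0001", 1, "A", "acute")
  assemble_run(rec, parsed, labels, e, root,
               reference_date = as.Date("2011-05-10"))
  snapshot <- function() {
    fs <- sort(list.files(root, recursive = TRUE))
    lapply(fs, function(f) file_bytes(file.path(root, f)))
  }
  before <- snapshot()
  assemble_run(rec, parsed, labels, e, root,
               reference_date = as.Date("2011-05-10"))
  expect_identical(snapshot(), before)

  rec2 <- intraop_rec(seed = 99)
  expect_error(assemble_run(rec2, parsed, labels, e, root,
                            reference_date = as.Date("2011-05-10")),
               "entity collision")
})

test_that("channel counts agree across header, channels.tsv and sidecar", {
  root <- withr::local_tempdir()
  rec <- intraop_rec()
  parsed <- make_parsed(rec)
  e <- intraop_entities("RESP0002", 1, "A", "acute")
  assemble_run(rec, parsed, NULL, e, root,
               reference_date = as.Date("2011-05-10"))
  ieeg_dir <- file.path(root, "sub-RESP0002", "ses-SITUATION1A", "ieeg")
  stem <- "sub-RESP0002_ses-SITUATION1A_task-acute"
  vhdr <- readLines(file.path(ieeg_dir, paste0(stem, "_ieeg.vhdr")))
  n_vhdr <- as.integer(sub("NumberOfChannels=", "",
                           grep("NumberOfChannels", vhdr, value = TRUE)))
  ct <- read.delim(file.path(ieeg_dir, paste0(stem, "_channels.tsv")))
  js <- jsonlite::read_json(file.path(ieeg_dir, paste0(stem, "_ieeg.json")))
  expect_equal(n_vhdr, nrow(rec$channels))
  expect_equal(nrow(ct), n_vhdr)
  expect_equal(js$ECOGChannelCount + js$SEEGChannelCount,
               sum(ct$type %in% c("ECOG", "SEEG")))
})
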