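# ---------------------------------------------------------------------------
# BIDS assembly: entity naming for the two study arms, sidecar generation,
# BrainVision signal export, scans/participants bookkeeping and sourcedata
# layout.
#
# Two arms:
#   * intraoperative: one BIDS session per surgical "situation"
#     (ses-SITUATION1A ... pre-resection, 2A ... intermediate, 3A the final
#     post-resection recording), task in {acute, SSEP, stimulation}, no run.
#   * long-term monitoring: one session per monitoring period (ses-1, with
#     1a/1b splits when electrodes change), run label DDHHMM where DD is the
#     day after implantation (implantation day = 01) and HHMM the wall-clock
#     start time.
#
# All dates written into the tree are shifted so that the reference date
# (implantation or surgery) maps to 1900-01-01; day and time deltas are
# preserved, the true calendar is not.
# ---------------------------------------------------------------------------

INTRAOP_TASKS <- c("acute", "SSEP", "stimulation")
LONGTERM_TASKS <- c("rest", "sleep", "SPESclin", "motor", "language", "SSEP",
                    "seizure")

#' BIDS entities for one run
#'
#' Use [intraop_entities()] or [longterm_entities()] rather than calling this
#' directly.
#'
#' @param sub Subject label (`RESP####`).
#' @param ses Session label.
#' @param task Task label.
#' @param run Optional 6-digit `DDHHMM` run label (long-term arm only).
#' @param arm `"intraop"` or `"longterm"`.
#' @return Object of class `bids_entities`.
#' @export
bids_entities <- function(sub, ses, task, run = NULL,
                          arm = c("intraop", "longterm")) {
  arm <- match.arg(arm)
  if (!grepl(RESP_ID_RE, sub)) stop("subject label must match RESP####: ", sub)
  if (arm == "intraop") {
    if (!grepl("^SITUATION[1-9][0-9]*[A-Z]$", ses)) {
      stop("intraoperative session label must match SITUATION<number><letter>: ",
           ses)
    }
    if (!task %in% INTRAOP_TASKS) {
      stop("intraoperative task must be one of ",
           paste(INTRAOP_TASKS, collapse = ", "), ": ", task)
    }
    if (!is.null(run)) stop("intraoperative recordings do not use a run entity")
  } else {
    if (!grepl("^[1-9][0-9]*[a-z]?$", ses)) {
      stop("long-term session label must match 1, 1a, 1b, 2, ...: ", ses)
    }
    if (!task %in% LONGTERM_TASKS) {
      stop("long-term task must be one of ",
           paste(LONGTERM_TASKS, collapse = ", "), ": ", task)
    }
    if (is.null(run) || !grepl("^[0-9]{6}$", run)) {
      stop("long-term recordings need a 6-digit DDHHMM run label")
    }
  }
  structure(list(sub = sub, ses = ses, task = task, run = run, arm = arm),
            class = "bids_entities")
}

#' Entities for an intraoperative situation
#'
#' Situations are numbered by surgical stage (1 = pre-resection, increasing
#' through intermediate stages, highest = post-resection) and lettered by
#' electrode configuration within a stage.
#'
#' @param resp_id Subject label.
#' @param situation_number Stage number, >= 1.
#' @param situation_letter Single letter `A`-`Z`.
#' @param task One of `acute`, `SSEP`, `stimulation`.
#' @return A [bids_entities()].
#' @export
#' @examples
#' intraop_entities("RESP0384", 1, "A", "acute")
intraop_entities <- function(resp_id, situation_number, situation_letter,
                             task = "acute") {
  if (!grepl("^[A-Z]$", situation_letter)) {
    stop("situation letter must be a single character A-Z, got: ",
         situation_letter)
  }
  if (situation_number < 1) stop("situation number starts from 1")
  bids_entities(resp_id,
                sprintf("SITUATION%d%s", as.integer(situation_number),
                        situation_letter),
                task, run = NULL, arm = "intraop")
}

#' Entities for a long-term monitoring run
#'
#' @param resp_id Subject label.
#' @param ses Session label (`1`, `1a`, `1b`, `2`, ...).
#' @param task Long-term task label.
#' @param run 6-digit `DDHHMM` run label, see [longterm_run_label()].
#' @return A [bids_entities()].
#' @export
longterm_entities <- function(resp_id, ses, task, run) {
  bids_entities(resp_id, ses, task, run = run, arm = "longterm")
}

#' Encode a long-term run label
#'
#' `DDHHMM`: `DD` is the consecutive day after implantation with the
#' implantation day itself being day 01, `HHMM` the wall-clock start time.
#' A recording starting at 13:15 on the day after implantation is
#' `"021315"`.
#'
#' @param implantation_date `Date` (or coercible) of electrode implantation.
#' @param rec_start `POSIXct` recording start.
#' @return 6-character run label.
#' @export
longterm_run_label <- function(implantation_date, rec_start) {
  implantation_date <- as.Date(implantation_date)
  rec_start <- as.POSIXct(rec_start, tz = "UTC")
  delta <- as.integer(as.Date(rec_start, tz = "UTC") - implantation_date)
  if (delta < 0) stop("recording starts before the implantation date")
  dd <- delta + 1L
  if (dd > 99L) stop("day index ", dd, " exceeds the 2-digit run encoding; ",
                     "monitoring periods span days, not months")
  lt <- as.POSIXlt(rec_start, tz = "UTC")
  sprintf("%02d%02d%02d", dd, lt$hour, lt$min)
}

# sub-..._ses-..._task-...[_run-...] stem
entity_stem <- function(e) {
  stem <- sprintf("sub-%s_ses-%s_task-%s", e$sub, e$ses, e$task)
  if (!is.null(e$run)) stem <- paste0(stem, "_run-", e$run)
  stem
}

#' Shift an acquisition time to the anonymized calendar
#'
#' The reference date (implantation or surgery day) maps to 1900-01-01;
#' day and wall-time deltas are preserved.
#'
#' @param rec_start `POSIXct` true acquisition start.
#' @param reference_date The true reference `Date`.
#' @return ISO 8601 string in the shifted calendar.
#' @export
shift_acq_time <- function(rec_start, reference_date) {
  rec_start <- as.POSIXct(rec_start, tz = "UTC")
  delta_days <- as.integer(as.Date(rec_start, tz = "UTC") - as.Date(reference_date))
  lt <- as.POSIXlt(rec_start, tz = "UTC")
  shifted <- as.Date("1900-01-01") + delta_days
  sprintf("%sT%02d:%02d:%02d", format(shifted, "%Y-%m-%d"),
          lt$hour, lt$min, round(lt$sec))
}

# -- channels.tsv ------------------------------------------------------------

STATUS_DESCRIPTIONS <- c(bad = "noisy after visual inspection",
                         silicon = "electrode on top of other electrode",
                         screw = "located in screw")

DEFAULT_PREFIX_TYPES <- c(ECG = "ECG", EKG = "ECG", EMG = "EMG")

#' Build the channels table for one run
#'
#' Channel type comes from the electrode group the channel belongs to (grid
#' and strip contacts are ECOG, depth contacts SEEG); channels outside the
#' declared groups are typed by name prefix (`ECG`, `EMG`, else `OTHER`).
#' Status marks from the annotation grammar map to BIDS status /
#' status_description: `Bad` -> bad / "noisy after visual inspection",
#' `Silicon` -> bad / "electrode on top of other electrode", `Screw` -> bad /
#' "located in screw"; unmarked channels are good with description `"n/a"`.
#'
#' @param rec A [trc_recording()].
#' @param parsed A [parse_annotations()] result (status marks).
#' @param groups A [format_spec()] declaring the electrode layout.
#' @param prefix_types Named map from label prefix to BIDS type for non-iEEG
#'   channels.
#' @return `data.frame` with the BIDS channels.tsv columns.
#' @export
build_channels <- function(rec, parsed, groups,
                           prefix_types = DEFAULT_PREFIX_TYPES) {
  labels <- rec$channels$label
  group_of <- stats::setNames(
    rep(vapply(groups$groups, `[[`, "", "name"),
        vapply(groups$groups, function(g) g$rows * g$cols, integer(1))),
    contact_labels(groups))
  gtype_of <- stats::setNames(
    rep(vapply(groups$groups, `[[`, "", "gtype"),
        vapply(groups$groups, function(g) g$rows * g$cols, integer(1))),
    contact_labels(groups))

  type <- vapply(labels, function(lb) {
    if (lb %in% names(gtype_of)) {
      if (gtype_of[[lb]] == "depth") "SEEG" else "ECOG"
    } else {
      hit <- which(startsWith(toupper(lb), names(prefix_types)))
      if (length(hit)) prefix_types[[hit[1]]] else "OTHER"
    }
  }, character(1))

  status <- rep("good", length(labels))
  descr <- rep("n/a", length(labels))
  if (nrow(parsed$statuses)) {
    unknown <- setdiff(parsed$statuses$channel, labels)
    if (length(unknown)) {
      stop("status mark names unknown channels: ",
           paste(unknown, collapse = ", "))
    }
    for (i in seq_len(nrow(parsed$statuses))) {
      j <- match(parsed$statuses$channel[i], labels)
      status[j] <- "bad"
      descr[j] <- STATUS_DESCRIPTIONS[[parsed$statuses$kind[i]]]
    }
  }
  data.frame(name = labels, type = type,
             units = rec$channels$physical_unit,
             low_cutoff = "n/a", high_cutoff = "n/a",
             sampling_frequency = rec$channels$sampling_rate,
             status = status, status_description = descr,
             stringsAsFactors = FALSE)
}

# -- events.tsv --------------------------------------------------------------

#' Build the events table from paired segments
#'
#' @param segments Output of [pair_segments()] / `parsed$segments`.
#' @param fs Sampling rate in Hz.
#' @return `data.frame` with columns `onset`, `duration`, `trial_type`,
#'   `sample_start`, `sample_end`, `channels`; sorted by onset then
#'   trial_type.
#' @export
build_events <- function(segments, fs) {
  stopifnot(fs > 0)
  if (!nrow(segments)) {
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      trial_type = character(0), sample_start = integer(0),
                      sample_end = integer(0), channels = character(0),
                      stringsAsFactors = FALSE))
  }
  long <- ifelse(segments$code %in% names(SEGMENT_LONG_NAMES),
                 SEGMENT_LONG_NAMES[segments$code], segments$code)
  ev <- data.frame(onset = segments$onset_sample / fs,
                   duration = (segments$offset_sample - segments$onset_sample) / fs,
                   trial_type = unname(long),
                   sample_start = segments$onset_sample,
                   sample_end = segments$offset_sample,
                   channels = ifelse(nzchar(segments$channels),
                                     segments$channels, "n/a"),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset, ev$trial_type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# -- electrodes.tsv ----------------------------------------------------------

#' Build the electrodes table for one session
#'
#' One row per contact declared in the electrode format.  Intraoperative
#' sessions carry zeroed coordinates (positions live on the situation photo,
#' referenced from coordsystem.json); long-term sessions carry mm
#' coordinates.  The resected/edge/cavity labels are written as yes/no
#' columns.
#'
#' @param groups A [format_spec()].
#' @param labels A `label_set` from [classify_2d()]/[classify_3d()], or
#'   `NULL` for all-no labels.
#' @param coords Named n x 3 matrix of mm coordinates (rownames = contact
#'   labels), or `NULL` for the intraoperative zero convention.
#' @param contact_radius Contact radius in mm used for the `size` column
#'   (`pi * r^2`, 2 decimals).
#' @return `data.frame` with the BIDS electrodes.tsv columns.
#' @export
build_electrodes <- function(groups, labels = NULL, coords = NULL,
                             contact_radius = 2) {
  contacts <- contact_labels(groups)
  group <- rep(vapply(groups$groups, `[[`, "", "name"),
               vapply(groups$groups, function(g) g$rows * g$cols, integer(1)))
  yn <- function(lgl) ifelse(lgl, "yes", "no")
  res <- edge <- cav <- rep(FALSE, length(contacts))
  if (!is.null(labels)) {
    j <- match(contacts, labels$label)
    res[!is.na(j)] <- labels$resected[j[!is.na(j)]]
    edge[!is.na(j)] <- labels$edge[j[!is.na(j)]]
    cav[!is.na(j)] <- labels$cavity[j[!is.na(j)]]
  }
  if (is.null(coords)) {
    x <- y <- z <- rep(0, length(contacts))
  } else {
    j <- match(contacts, rownames(coords))
    if (anyNA(j)) {
      stop("coordinates missing for contacts: ",
           paste(contacts[is.na(j)], collapse = ", "))
    }
    x <- coords[j, 1]; y <- coords[j, 2]; z <- coords[j, 3]
  }
  data.frame(name = contacts, x = x, y = y, z = z,
             size = sprintf("%.2f", pi * contact_radius^2),
             group = group, resected = yn(res), edge = yn(edge),
             cavity = yn(cav), stringsAsFactors = FALSE)
}

# -- _ieeg.json --------------------------------------------------------------

#' Build the _ieeg.json sidecar
#'
#' @param rec A [trc_recording()].
#' @param parsed A [parse_annotations()] result; its format declaration is
#'   mandatory and becomes `iEEGElectrodeGroups` in canonical form.
#' @param entities A [bids_entities()].
#' @param channels The [build_channels()] table (for ECOG/SEEG counts).
#' @param manufacturer Acquisition system manufacturer.
#' @return Named list ready for JSON serialization.
#' @export
build_ieeg_json <- function(rec, parsed, entities, channels,
                            manufacturer = "Micromed") {
  if (is.null(parsed$format)) {
    stop("recording has no electrode format declaration; ",
         "every converted file must declare one")
  }
  list(
    TaskName = entities$task,
    SamplingFrequency = sampling_rate(rec),
    PowerLineFrequency = 50,
    SoftwareFilters = "n/a",
    HardwareFilters = "n/a",
    Manufacturer = manufacturer,
    RecordingDuration = recording_duration(rec),
    RecordingType = "continuous",
    iEEGReference = "n/a",
    ECOGChannelCount = sum(channels$type == "ECOG"),
    SEEGChannelCount = sum(channels$type == "SEEG"),
    ECGChannelCount = sum(channels$type == "ECG"),
    EMGChannelCount = sum(channels$type == "EMG"),
    MiscChannelCount = sum(channels$type == "OTHER"),
    iEEGElectrodeGroups = canonical_format_string(parsed$format)
  )
}

# -- BrainVision writer ------------------------------------------------------

bv_resolution <- function(channels) {
  res <- pmax(abs(channels$phys_min), abs(channels$phys_max)) / 32767
  if (any(res <= 0)) stop("degenerate physical range; cannot pick a resolution")
  res
}

#' Write a recording as a BrainVision triplet
#'
#' Emits `.vhdr` (text header), `.eeg` (multiplexed signed 16-bit binary)
#' and `.vmrk` (one New Segment marker holding the shifted start time).  The
#' per-channel resolution is chosen as `max(|phys range|) / 32767` so that
#' physical values survive the round trip within one least significant bit.
#'
#' @param rec A [trc_recording()].
#' @param base Path stem; `.vhdr`, `.eeg`, `.vmrk` are appended.
#' @param acq_time Shifted ISO 8601 acquisition time for the marker file.
#' @return Character vector of the three paths, invisibly.
#' @export
write_brainvision <- function(rec, base, acq_time = "1900-01-01T00:00:00") {
  phys <- trc_physical(rec)
  res <- bv_resolution(rec$channels)
  values <- round(phys / res)
  if (any(abs(values) > 32767)) {
    stop("physical range is not representable in 16 bits at the chosen resolution")
  }
  stem <- basename(base)
  vhdr <- paste0(base, ".vhdr"); eeg <- paste0(base, ".eeg")
  vmrk <- paste0(base, ".vmrk")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; Converted from a Micromed-style TRC recording",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$channels)),
    paste0("SamplingInterval=", format(1e6 / sampling_rate(rec), scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%.12g,%s", seq_len(nrow(rec$channels)),
            rec$channels$label, res,
            ifelse(rec$channels$physical_unit == "uV", "µV", "mV"))
  )
  writeLines(hdr, vhdr, useBytes = FALSE)

  con <- file(eeg, "wb")
  writeBin(as.integer(as.vector(values)), con, size = 2, endian = "little")
  close(con)

  marker_date <- paste0(gsub("[-T:]", "", acq_time), "000000")
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "",
    "[Marker Infos]",
    paste0("Mk1=New Segment,,1,1,0,", marker_date)
  )
  writeLines(mrk, vmrk)
  invisible(c(vhdr = vhdr, eeg = eeg, vmrk = vmrk))
}

#' Read back a BrainVision triplet
#'
#' Minimal reader for round-trip verification: parses the channel lines and
#' binary layout of the `.vhdr` and reconstructs the physical signal matrix.
#'
#' @param vhdr Path to the `.vhdr` file.
#' @return List with `labels`, `resolution`, `sampling_rate` and `phys`
#'   (channels x time matrix).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, encoding = "UTF-8")
  get1 <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  n_ch <- as.integer(get1("NumberOfChannels"))
  si <- as.numeric(get1("SamplingInterval"))
  stopifnot(identical(get1("DataOrientation"), "MULTIPLEXED"),
            identical(get1("BinaryFormat"), "INT_16"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[`, "", 1)
  res <- as.numeric(vapply(parts, `[`, "", 3))
  eeg <- file.path(dirname(vhdr), get1("DataFile"))
  n_vals <- file.info(eeg)$size / 2
  con <- file(eeg, "rb")
  raw_vals <- readBin(con, "integer", n_vals, size = 2, signed = TRUE,
                      endian = "little")
  close(con)
  m <- matrix(raw_vals, nrow = n_ch)
  list(labels = labels, resolution = res, sampling_rate = 1e6 / si,
       phys = m * res)
}

# -- deterministic file writers ----------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a", eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, colClasses = "character", na.strings = NULL)
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# write bytes/generator output unless an identical file already exists;
# error on a conflicting existing file (entity collision)
write_guarded <- function(path, writer) {
  if (!file.exists(path)) {
    writer(path)
    return(invisible(TRUE))
  }
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(path)))
  on.exit(unlink(tmp))
  writer(tmp)
  same <- identical(readBin(tmp, "raw", file.info(tmp)$size),
                    readBin(path, "raw", file.info(path)$size))
  if (!same) {
    stop("entity collision: ", path,
         " already exists with different content")
  }
  invisible(FALSE)
}

# -- dataset-level bookkeeping ----------------------------------------------

ensure_dataset_root <- function(root, name) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dd <- file.path(root, "dataset_description.json")
  if (!file.exists(dd)) {
    write_json_sidecar(list(Name = name, BIDSVersion = "1.7.0",
                            DatasetType = "raw",
                            Authors = list("ieegcurate")), dd)
  }
  invisible(root)
}

update_participants <- function(root, sub, sex = "n/a", age = "n/a") {
  path <- file.path(root, "participants.tsv")
  df <- if (file.exists(path)) read_tsv(path) else
    data.frame(participant_id = character(0), number_of_sessions = character(0),
               sex = character(0), age = character(0), stringsAsFactors = FALSE)
  pid <- paste0("sub-", sub)
  n_ses <- length(list.dirs(file.path(root, pid), recursive = FALSE))
  row <- data.frame(participant_id = pid,
                    number_of_sessions = as.character(n_ses),
                    sex = sex, age = as.character(age), stringsAsFactors = FALSE)
  df <- df[df$participant_id != pid, , drop = FALSE]
  df <- rbind(df, row)
  df <- df[order(df$participant_id), , drop = FALSE]
  write_tsv(df, path)
  pj <- file.path(root, "participants.json")
  if (!file.exists(pj)) {
    write_json_sidecar(list(
      participant_id = list(Description = "RESP study code"),
      number_of_sessions = list(Description = "number of ses- directories"),
      sex = list(Description = "patient sex, m/f/n/a"),
      age = list(Description = "age in years at first recording")), pj)
  }
  invisible(path)
}

scan_count_columns <- function() {
  c("sleep", "seizure", "artefact", "good_segment", "electrical_stimulation",
    "motor_task", "language_task", "ssep", "rest")
}

update_scans <- function(ses_dir, sub, ses, filename, acq_time, events) {
  path <- file.path(ses_dir, sprintf("sub-%s_ses-%s_scans.tsv", sub, ses))
  cols <- scan_count_columns()
  df <- if (file.exists(path)) read_tsv(path) else {
    d <- data.frame(filename = character(0), acq_time = character(0),
                    stringsAsFactors = FALSE)
    for (cc in cols) d[[cc]] <- character(0)
    d
  }
  counts <- vapply(cols, function(cc) sum(events$trial_type == cc), integer(1))
  row <- data.frame(filename = filename, acq_time = acq_time,
                    stringsAsFactors = FALSE)
  for (cc in cols) row[[cc]] <- as.character(counts[[cc]])
  df <- df[df$filename != filename, , drop = FALSE]
  df <- rbind(df, row)
  df <- df[order(df$filename), , drop = FALSE]
  write_tsv(df, path)
  sj <- file.path(ses_dir, sprintf("sub-%s_ses-%s_scans.json", sub, ses))
  if (!file.exists(sj)) {
    desc <- c(list(filename = list(Description = "relative ieeg file path"),
                   acq_time = list(Description = "date-shifted acquisition start")),
              stats::setNames(lapply(cols, function(cc)
                list(Description = paste("number of", cc, "events in the file"))),
                cols))
    write_json_sidecar(desc, sj)
  }
  invisible(path)
}

events_json_descriptor <- function() {
  list(
    onset = list(Description = "event onset from recording start", Units = "s"),
    duration = list(Description = "event duration", Units = "s"),
    trial_type = list(
      Description = "event category from the annotation grammar",
      Levels = as.list(stats::setNames(
        c("period of sleep", "epileptic seizure", "artefact",
          "good clean data segment", "single-pulse electrical stimulation",
          "motor task", "language task", "somatosensory evoked potentials",
          "resting state"),
        unname(SEGMENT_LONG_NAMES)))),
    sample_start = list(Description = "0-based onset sample"),
    sample_end = list(Description = "0-based exclusive offset sample"),
    channels = list(Description = "';'-joined channels involved, n/a for all")
  )
}

# -- run assembly ------------------------------------------------------------

#' Assemble one BIDS run
#'
#' Writes the BrainVision triplet, `_ieeg.json`, `_channels.tsv`,
#' `_events.tsv` and `_events.json` for the run; creates or updates the
#' session-level `_electrodes.tsv`, `_coordsystem.json` and `_scans.tsv`, the
#' root `participants.tsv` and `dataset_description.json`; and mirrors the
#' pseudo-anonymized TRC plus photos/masks under `sourcedata/`.  Re-running
#' with identical inputs changes no bytes; a run name that already exists
#' with different content is an entity collision error.
#'
#' @param rec Pseudo-anonymized [trc_recording()].
#' @param parsed [parse_annotations()] result for `rec`.
#' @param labels `label_set` with resected/edge/cavity flags, or `NULL`.
#' @param entities A [bids_entities()].
#' @param root Dataset root directory.
#' @param reference_date True implantation/surgery date used to shift public
#'   dates to the 1900-01-01 calendar.
#' @param subject_info List with `sex` and `age` for participants.tsv.
#' @param coords Named n x 3 mm coordinate matrix for long-term sessions;
#'   `NULL` writes the intraoperative zero convention.
#' @param photo Situation photo filename recorded in coordsystem.json
#'   (intraoperative arm).
#' @param source_files Character vector of files (e.g. the scrubbed TRC,
#'   photos, masks) copied into `sourcedata/sub-<id>/ses-<label>/`.
#' @param contact_radius Contact radius in mm for the electrodes `size`
#'   column.
#' @param manufacturer Manufacturer string for `_ieeg.json`.
#' @param dataset_name Name written into a fresh dataset_description.json.
#' @return Character vector of files created or checked, invisibly.
#' @export
assemble_run <- function(rec, parsed, labels, entities, root,
                         reference_date,
                         subject_info = list(sex = "n/a", age = "n/a"),
                         coords = NULL, photo = NULL,
                         source_files = character(0),
                         contact_radius = 2, manufacturer = "Micromed",
                         dataset_name = "iEEG-BIDS dataset") {
  stopifnot(inherits(rec, "trc_recording"), inherits(entities, "bids_entities"))
  if (is.null(parsed$format)) {
    stop("cannot assemble a run without an electrode format declaration")
  }
  known <- c(contact_labels(parsed$format))
  aux <- setdiff(rec$channels$label, known)
  bad_aux <- aux[!grepl("^(ECG|EKG|EMG|MKR|OTHER)", toupper(aux))]
  if (length(bad_aux)) {
    stop("recorded channels absent from the electrode format and not ",
         "recognisable as auxiliary: ", paste(bad_aux, collapse = ", "))
  }

  ensure_dataset_root(root, dataset_name)
  sub_dir <- file.path(root, paste0("sub-", entities$sub))
  ses_dir <- file.path(sub_dir, paste0("ses-", entities$ses))
  ieeg_dir <- file.path(ses_dir, "ieeg")
  dir.create(ieeg_dir, recursive = TRUE, showWarnings = FALSE)

  stem <- entity_stem(entities)
  acq_time <- shift_acq_time(rec$recording_start, reference_date)
  created <- character(0)
  track <- function(p) created <<- c(created, p)

  # signal: BrainVision triplet (guarded as a unit)
  base <- file.path(ieeg_dir, paste0(stem, "_ieeg"))
  if (any(file.exists(paste0(base, c(".vhdr", ".eeg", ".vmrk"))))) {
    tmpbase <- file.path(tempdir(), paste0(stem, "_ieeg_probe"))
    write_brainvision(rec, tmpbase, acq_time)
    on.exit(unlink(paste0(tmpbase, c(".vhdr", ".eeg", ".vmrk"))), add = TRUE)
    for (ext in c(".vhdr", ".eeg", ".vmrk")) {
      old <- paste0(base, ext); new <- paste0(tmpbase, ext)
      probe <- readBin(new, "raw", file.info(new)$size)
      # the probe header names the probe stem; normalize before comparing
      if (ext != ".eeg") {
        probe <- charToRaw(gsub(basename(tmpbase), paste0(stem, "_ieeg"),
                                rawToChar(probe), fixed = TRUE,
                                useBytes = TRUE))
      }
      if (!file.exists(old) ||
          !identical(probe, readBin(old, "raw", file.info(old)$size))) {
        stop("entity collision: ", old, " already exists with different content")
      }
    }
  } else {
    write_brainvision(rec, base, acq_time)
  }
  track(paste0(base, c(".vhdr", ".eeg", ".vmrk")))

  channels <- build_channels(rec, parsed, parsed$format)
  write_guarded(file.path(ieeg_dir, paste0(stem, "_channels.tsv")),
                function(p) write_tsv(channels, p))
  track(file.path(ieeg_dir, paste0(stem, "_channels.tsv")))

  events <- build_events(parsed$segments, sampling_rate(rec))
  write_guarded(file.path(ieeg_dir, paste0(stem, "_events.tsv")),
                function(p) write_tsv(events, p))
  write_guarded(file.path(ieeg_dir, paste0(stem, "_events.json")),
                function(p) write_json_sidecar(events_json_descriptor(), p))
  track(file.path(ieeg_dir, paste0(stem, c("_events.tsv", "_events.json"))))

  sidecar <- build_ieeg_json(rec, parsed, entities, channels, manufacturer)
  write_guarded(file.path(ieeg_dir, paste0(stem, "_ieeg.json")),
                function(p) write_json_sidecar(sidecar, p))
  track(file.path(ieeg_dir, paste0(stem, "_ieeg.json")))

  # session-level electrodes + coordsystem
  ses_stem <- sprintf("sub-%s_ses-%s", entities$sub, entities$ses)
  electrodes <- build_electrodes(parsed$format, labels, coords, contact_radius)
  write_guarded(file.path(ieeg_dir, paste0(ses_stem, "_electrodes.tsv")),
                function(p) write_tsv(electrodes, p))
  coordsys <- if (is.null(coords)) {
    list(iEEGCoordinateSystem = "Other",
         iEEGCoordinateUnits = "mm",
         iEEGCoordinateSystemDescription = paste(
           "Coordinates are withheld (all zero); electrode positions are",
           "documented on the referenced intraoperative photo, on which",
           "contact numbering matches the electrode names."),
         IntendedFor = if (is.null(photo)) "n/a" else photo)
  } else {
    list(iEEGCoordinateSystem = "Other",
         iEEGCoordinateUnits = "mm",
         iEEGCoordinateSystemDescription = paste(
           "Patient-specific space: electrodes localized on the",
           "post-implantation CT co-registered to the pre-operative MRI."),
         IntendedFor = if (is.null(photo)) "n/a" else photo)
  }
  write_guarded(file.path(ieeg_dir, paste0(ses_stem, "_coordsystem.json")),
                function(p) write_json_sidecar(coordsys, p))
  track(file.path(ieeg_dir, paste0(ses_stem,
                                   c("_electrodes.tsv", "_coordsystem.json"))))

  rel_ieeg <- file.path("ieeg", paste0(stem, "_ieeg.vhdr"))
  update_scans(ses_dir, entities$sub, entities$ses, rel_ieeg, acq_time, events)
  update_participants(root, entities$sub, subject_info$sex, subject_info$age)

  if (length(source_files)) {
    src_dir <- file.path(root, "sourcedata", paste0("sub-", entities$sub),
                         paste0("ses-", entities$ses))
    dir.create(src_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in source_files) {
      dst <- file.path(src_dir, basename(f))
      if (!file.exists(dst) ||
          !identical(readBin(f, "raw", file.info(f)$size),
                     readBin(dst, "raw", file.info(dst)$size))) {
        file.copy(f, dst, overwrite = TRUE)
      }
      track(dst)
    }
  }
  invisible(created)
}
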