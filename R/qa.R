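# ---------------------------------------------------------------------------
# Structural validation of produced datasets and generation of a fully
# synthetic demonstration study (intraoperative + long-term arms).
#
# The validator is a lightweight structural checker with stable error codes;
# it complements, and does not replace, the official BIDS validator.
# ---------------------------------------------------------------------------

IEEG_STEM_RE <- paste0(
  "^sub-RESP[0-9]{4}_ses-(SITUATION[1-9][0-9]*[A-Z]|[1-9][0-9]*[a-z]?)",
  "_task-[A-Za-z0-9]+(_run-[0-9]+)?_ieeg\\.vhdr$")

issue_row <- function(code, severity, path, message) {
  data.frame(code = code, severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)
}

#' Structurally validate an iEEG-BIDS dataset
#'
#' Checks filename entities, presence of the per-run sidecars, channel-count
#' consistency between `_channels.tsv`, the BrainVision header and
#' `_ieeg.json`, event bounds against the recording duration, the
#' `electrodes.tsv` column contract including resected/edge/cavity, the
#' zero-coordinate convention for intraoperative sessions, the `DDHHMM` run
#' label format, the status/status_description pairing, and the
#' `participants.tsv` session counts.
#'
#' @param root Dataset root directory.
#' @return Object of class `validation_report`: `$issues` data.frame
#'   (`code`, `severity`, `path`, `message`) and `$passed` (no
#'   error-severity issues).
#' @export
validate_dataset <- function(root) {
  issues <- list()
  add <- function(code, severity, path, message) {
    issues[[length(issues) + 1]] <<- issue_row(code, severity, path, message)
  }
  if (!dir.exists(root)) {
    add("ROOT_MISSING", "error", root, "dataset root does not exist")
  } else {
    if (!file.exists(file.path(root, "dataset_description.json"))) {
      add("DATASET_DESCRIPTION_MISSING", "error",
          file.path(root, "dataset_description.json"),
          "dataset_description.json is required")
    }
    sub_dirs <- list.dirs(root, recursive = FALSE)
    sub_dirs <- sub_dirs[grepl("^sub-", basename(sub_dirs))]
    for (sd in sub_dirs) {
      if (!grepl("^sub-RESP[0-9]{4}$", basename(sd))) {
        add("SUBJECT_LABEL", "error", sd,
            "subject directory must be sub-RESP followed by 4 digits")
      }
      ses_dirs <- list.dirs(sd, recursive = FALSE)
      ses_dirs <- ses_dirs[grepl("^ses-", basename(ses_dirs))]
      if (!length(ses_dirs)) {
        add("NO_SESSIONS", "error", sd, "subject has no ses- directories")
      }
      for (ses in ses_dirs) validate_session(ses, add)
    }
    validate_participants(root, sub_dirs, add)
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    issue_row(character(0), character(0), character(0), character(0))
  structure(list(issues = issues,
                 passed = !any(issues$severity == "error")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s)\n",
              if (x$passed) "PASSED" else "FAILED",
              sum(x$issues$severity == "error"),
              sum(x$issues$severity == "warning")))
  if (nrow(x$issues)) print(x$issues)
  invisible(x)
}

validate_session <- function(ses_dir, add) {
  ses_label <- sub("^ses-", "", basename(ses_dir))
  sub_label <- sub("^sub-", "", basename(dirname(ses_dir)))
  intraop <- grepl("^SITUATION", ses_label)
  ieeg_dir <- file.path(ses_dir, "ieeg")
  if (!dir.exists(ieeg_dir)) {
    add("IEEG_DIR_MISSING", "error", ses_dir, "session has no ieeg/ directory")
    return(invisible())
  }
  vhdrs <- list.files(ieeg_dir, pattern = "_ieeg\\.vhdr$")
  if (!length(vhdrs)) {
    add("NO_RUNS", "error", ieeg_dir, "session has no _ieeg.vhdr files")
  }
  for (vh in vhdrs) {
    if (!grepl(IEEG_STEM_RE, vh)) {
      add("ENTITY_FORMAT", "error", file.path(ieeg_dir, vh),
          "filename does not match the sub/ses/task/run entity pattern")
      next
    }
    run <- regmatches(vh, regexpr("_run-[0-9]+", vh))
    if (length(run) && nzchar(run)) {
      digits <- sub("_run-", "", run)
      if (nchar(digits) != 6L) {
        add("RUN_LABEL_FORMAT", "error", file.path(ieeg_dir, vh),
            sprintf("run label '%s' must be 6 digits (DDHHMM)", digits))
      }
    } else if (!intraop) {
      add("RUN_LABEL_MISSING", "error", file.path(ieeg_dir, vh),
          "long-term recordings require a run entity")
    }
    validate_run(ieeg_dir, sub("\\.vhdr$", "", sub("_ieeg\\.vhdr$", "", vh)), add)
  }
  # session-level files
  ses_stem <- sprintf("sub-%s_ses-%s", sub_label, ses_label)
  elec <- file.path(ieeg_dir, paste0(ses_stem, "_electrodes.tsv"))
  if (!file.exists(elec)) {
    add("ELECTRODES_MISSING", "error", elec, "session electrodes.tsv is missing")
  } else {
    et <- read_tsv(elec)
    need <- c("name", "x", "y", "z", "size", "group", "resected", "edge",
              "cavity")
    missing <- setdiff(need, names(et))
    if (length(missing)) {
      add("ELECTRODES_COLUMNS", "error", elec,
          paste("missing columns:", paste(missing, collapse = ", ")))
    } else {
      if (!all(et$resected %in% c("yes", "no")) ||
          !all(et$edge %in% c("yes", "no")) ||
          !all(et$cavity %in% c("yes", "no"))) {
        add("ELECTRODES_LABEL_VALUES", "error", elec,
            "resected/edge/cavity must be yes or no")
      }
      if (any(et$cavity == "yes" &
              (et$resected == "yes" | et$edge == "yes"))) {
        add("CAVITY_PRECEDENCE", "error", elec,
            "cavity contacts cannot also be resected or edge")
      }
      if (intraop &&
          !all(as.numeric(et$x) == 0 & as.numeric(et$y) == 0 &
               as.numeric(et$z) == 0)) {
        add("INTRAOP_NONZERO_COORD", "error", elec,
            "intraoperative electrode coordinates must all be zero")
      }
    }
  }
  coord <- file.path(ieeg_dir, paste0(ses_stem, "_coordsystem.json"))
  if (!file.exists(coord)) {
    add("COORDSYSTEM_MISSING", "error", coord,
        "session coordsystem.json is missing")
  }
  scans <- file.path(ses_dir, paste0(ses_stem, "_scans.tsv"))
  if (!file.exists(scans)) {
    add("SCANS_MISSING", "error", scans, "session scans.tsv is missing")
  } else {
    st <- read_tsv(scans)
    for (f in st$filename) {
      if (!file.exists(file.path(ses_dir, f))) {
        add("SCANS_DANGLING", "error", scans,
            paste("scans.tsv references a missing file:", f))
      }
    }
  }
}

validate_run <- function(ieeg_dir, run_stem, add) {
  stem_path <- function(suffix) file.path(ieeg_dir, paste0(run_stem, suffix))
  required <- c("_ieeg.eeg", "_ieeg.vmrk", "_ieeg.json", "_channels.tsv",
                "_events.tsv")
  for (suffix in required) {
    if (!file.exists(stem_path(suffix))) {
      add("SIDECAR_MISSING", "error", stem_path(suffix),
          paste("required file is missing for run", run_stem))
    }
  }
  vhdr <- stem_path("_ieeg.vhdr")
  n_vhdr <- tryCatch({
    lines <- readLines(vhdr, warn = FALSE)
    as.integer(sub("^NumberOfChannels=", "",
                   grep("^NumberOfChannels=", lines, value = TRUE)[1]))
  }, error = function(e) NA_integer_)
  sidecar <- if (file.exists(stem_path("_ieeg.json"))) {
    jsonlite::read_json(stem_path("_ieeg.json"))
  } else NULL
  if (file.exists(stem_path("_channels.tsv"))) {
    ct <- read_tsv(stem_path("_channels.tsv"))
    if (!is.na(n_vhdr) && nrow(ct) != n_vhdr) {
      add("CHANNEL_COUNT_MISMATCH", "error", stem_path("_channels.tsv"),
          sprintf("channels.tsv has %d rows but the header declares %d",
                  nrow(ct), n_vhdr))
    }
    if (all(c("status", "status_description") %in% names(ct))) {
      bad_pairing <- xor(ct$status == "bad", ct$status_description != "n/a")
      if (any(bad_pairing)) {
        add("STATUS_DESCRIPTION_PAIRING", "error", stem_path("_channels.tsv"),
            "status=bad must pair with a status_description (and only then)")
      }
    }
    if (!is.null(sidecar)) {
      for (fld in c("ECOG", "SEEG")) {
        want <- sidecar[[paste0(fld, "ChannelCount")]]
        got <- sum(ct$type == fld)
        if (!is.null(want) && want != got) {
          add("IEEG_COUNT_MISMATCH", "error", stem_path("_ieeg.json"),
              sprintf("%sChannelCount is %d but channels.tsv has %d",
                      fld, want, got))
        }
      }
    }
  }
  if (file.exists(stem_path("_events.tsv")) && !is.null(sidecar)) {
    ev <- read_tsv(stem_path("_events.tsv"))
    if (nrow(ev)) {
      onset <- as.numeric(ev$onset); dur <- as.numeric(ev$duration)
      dur_total <- as.numeric(sidecar$RecordingDuration)
      if (any(onset < 0) ||
          any(onset + dur > dur_total + 1e-9)) {
        add("EVENT_BOUNDS", "error", stem_path("_events.tsv"),
            "events must satisfy 0 <= onset and onset+duration <= duration")
      }
    }
  }
}

validate_participants <- function(root, sub_dirs, add) {
  path <- file.path(root, "participants.tsv")
  if (!length(sub_dirs)) return(invisible())
  if (!file.exists(path)) {
    add("PARTICIPANTS_MISSING", "error", path,
        "participants.tsv is required when subjects are present")
    return(invisible())
  }
  pt <- read_tsv(path)
  for (sd in sub_dirs) {
    pid <- basename(sd)
    n_ses <- sum(grepl("^ses-", basename(list.dirs(sd, recursive = FALSE))))
    row <- pt[pt$participant_id == pid, , drop = FALSE]
    if (!nrow(row)) {
      add("PARTICIPANT_UNLISTED", "error", path,
          paste(pid, "has data but no participants.tsv row"))
    } else if (as.integer(row$number_of_sessions[1]) != n_ses) {
      add("SESSION_COUNT", "error", path,
          sprintf("%s lists %s sessions but has %d ses- directories",
                  pid, row$number_of_sessions[1], n_ses))
    }
  }
}

# -- demo study --------------------------------------------------------------

#' Specification of the synthetic demonstration study
#'
#' Mirrors the shared cohort composition: intraoperative subjects plus
#' long-term ECoG and SEEG subjects, split over two dataset roots.
#'
#' @param n_acute Number of intraoperative subjects.
#' @param n_longterm_ecog Number of long-term ECoG subjects.
#' @param n_longterm_seeg Number of long-term SEEG subjects.
#' @param seed Integer seed; the whole study is deterministic in it.
#' @return Object of class `demo_study_spec`.
#' @export
demo_study_spec <- function(n_acute = 6, n_longterm_ecog = 3,
                            n_longterm_seeg = 3, seed = 1) {
  stopifnot(n_acute >= 0, n_longterm_ecog >= 0, n_longterm_seeg >= 0)
  structure(list(n_acute = as.integer(n_acute),
                 n_longterm_ecog = as.integer(n_longterm_ecog),
                 n_longterm_seeg = as.integer(n_longterm_seeg),
                 seed = as.integer(seed)),
            class = "demo_study_spec")
}

# synthetic hospital identities; these names form the anonymization denylist
DEMO_SURNAMES <- c("Vermeer", "Jansen", "Bakker", "Devries", "Visser",
                   "Mulder", "Smit", "Meijer", "Deboer", "Vandijk",
                   "Peters", "Hendriks", "Dekker", "Brouwer", "Willems",
                   "Vos")
DEMO_GIVEN <- c("Anna", "Pieter", "Sanne", "Daan", "Lotte", "Bram", "Femke",
                "Joris", "Mara", "Thijs", "Iris", "Koen", "Nina", "Ruben",
                "Evi", "Lars")

demo_identity <- function(i) {
  k <- ((i - 1) %% length(DEMO_SURNAMES)) + 1
  list(surname = DEMO_SURNAMES[k], given = DEMO_GIVEN[k],
       hospital_id = sprintf("UMC-%05d", 31400 + i * 7),
       birth_year = 1960 + (i * 13) %% 40,
       sex = c("m", "f")[(i %% 2) + 1])
}

# 4 x 5 grid plan, 10 mm pitch, labels Gr01..Gr20 row-major
demo_grid_plan <- function() {
  idx <- seq_len(20)
  row <- ceiling(idx / 5); col <- (idx - 1) %% 5 + 1
  electrode_plan(sprintf("Gr%02d", idx), x = (col - 1) * 10,
                 y = (row - 1) * 10)
}

# irregular quadrilateral resection in the photo plane, jittered by subject
demo_resection_outline <- function(jitter, photo) {
  resection_outline(rbind(c(-6 + jitter[1], -6 + jitter[2]),
                          c(16 + jitter[3], -4 + jitter[4]),
                          c(14 + jitter[5], 34 + jitter[6]),
                          c(-8 + jitter[7], 32 + jitter[8])),
                    provenance = photo)
}

demo_acute_subject <- function(i, resp_id, identity, root, registry_denylist) {
  n_sit <- 2 + (i * 3) %% 8                     # 2..9 situations
  n_pre <- min(4, max(1, n_sit - 1 - (i %% 3))) # >= 1 pre-resection
  n_mid <- n_sit - n_pre - 1                    # rest intermediate
  post_number <- if (n_mid > 0) 3L else 2L
  surgery_date <- as.Date("2011-05-10") + i * 17

  sits <- list()
  for (k in seq_len(n_pre)) sits <- c(sits, list(c(1L, k)))
  for (k in seq_len(n_mid)) sits <- c(sits, list(c(2L, k)))
  sits <- c(sits, list(c(post_number, 1L)))

  plan <- demo_grid_plan()
  outline <- demo_resection_outline(stats::runif(8, -2, 2),
                                    photo = sprintf("%s_surgery_photo.jpg", resp_id))
  cavities <- if (i %% 3 == 0) {
    list(resection_outline(rbind(c(32, 24), c(44, 24), c(44, 36), c(32, 36))))
  } else list()
  labels <- classify_2d(plan, outline, cavities)

  for (s in seq_along(sits)) {
    num <- sits[[s]][1]; letter <- LETTERS[sits[[s]][2]]
    start <- as.POSIXct(paste(surgery_date, "09:00:00"), tz = "UTC") +
      (s - 1) * 1800
    fs <- 512L
    good_on <- fs; good_off <- 3L * fs
    notes <- rbind(
      trc_note(0L, "Format;Gr[4 x 5]"),
      trc_note(0L, sprintf("Bad;Gr%02d", (i + s) %% 20 + 1)),
      trc_note(good_on, "Good_on"),
      trc_note(good_off, "Good_off"),
      trc_note(0L, sprintf("situation %d%s check by surgeon", num, letter))
    )
    spec <- signal_spec(
      labels = plan$label, rate = fs, duration_s = 4,
      noise_sd = 6, spike_times = c(0.8, 2.2),
      burst_suppression = (num == 1 && letter == "A"),
      patient = patient_header(identity$surname, identity$given,
                               14, 7, identity$birth_year,
                               free_text_fields = data.frame(
                                 id = 1L,
                                 text = paste0(identity$surname, "-avg montage"),
                                 stringsAsFactors = FALSE)),
      recording_start = start, notes = notes)
    rec <- synthesize_recording(spec, seed = i * 1000 + s)

    anon <- pseudo_anonymize(rec, resp_id,
                             denylist = c(identity$surname, identity$given))
    stopifnot(nrow(anon$report$residual_findings) == 0)
    parsed <- parse_annotations(anon$recording$notes, n_samples(anon$recording))
    entities <- intraop_entities(resp_id, num, letter, "acute")

    src_dir <- file.path(tempdir(), "ieegcurate-demo-src")
    dir.create(src_dir, showWarnings = FALSE)
    trc_path <- file.path(src_dir, paste0(entity_stem(entities), ".TRC"))
    write_trc(anon$recording, trc_path)
    geo_path <- file.path(src_dir, paste0(resp_id, "_resection_outline.geojson"))
    write_outline_geojson(outline, geo_path)

    assemble_run(anon$recording, parsed, labels, entities, root,
                 reference_date = surgery_date,
                 subject_info = list(
                   sex = identity$sex,
                   age = as.integer(format(surgery_date, "%Y")) - identity$birth_year),
                 photo = sprintf("%s_ses-%s_photo.jpg", resp_id,
                                 sprintf("SITUATION%d%s", num, letter)),
                 source_files = c(trc_path, geo_path),
                 dataset_name = "Synthetic acute iEEG demonstration study")
  }
  invisible(NULL)
}

demo_longterm_layout <- function(kind) {
  if (kind == "ecog") {
    fmt <- parse_format("ECoG;C[4x8];CH[2x8];strip;IHa[1x8];IHv[1x8]")
    labels <- contact_labels(fmt)
    coords <- matrix(NA_real_, nrow = length(labels), ncol = 3,
                     dimnames = list(labels, NULL))
    place <- function(prefix, n, origin, step) {
      for (k in seq_len(n)) {
        coords[sprintf("%s%02d", prefix, k), ] <<- origin + (k - 1) * step
      }
    }
    # compact synthetic geometry inside the mask grid (not anatomical)
    for (r in 1:4) {
      for (k in 1:8) {
        coords[sprintf("C%02d", (r - 1) * 8 + k), ] <-
          c(4 + 5 * (k - 1), 6 + 5 * r, 18)
      }
    }
    for (r in 1:2) {
      for (k in 1:8) {
        coords[sprintf("CH%02d", (r - 1) * 8 + k), ] <-
          c(4 + 5 * (k - 1), 34 + 4 * r, 22)
      }
    }
    place("IHa", 8, c(20, 4, 6), c(0, 0, 4))
    place("IHv", 8, c(26, 4, 6), c(0, 0, 4))
    list(fmt_string = "ECoG;C[4x8];CH[2x8];strip;IHa[1x8];IHv[1x8]",
         fmt = fmt, coords = coords)
  } else {
    fmt <- parse_format("SEEG;Am[1x8];Ah[1x8];Ap[1x8];Ip[1x8]")
    labels <- contact_labels(fmt)
    coords <- matrix(NA_real_, nrow = length(labels), ncol = 3,
                     dimnames = list(labels, NULL))
    origins <- list(Am = c(6, 10, 10), Ah = c(6, 18, 14), Ap = c(6, 26, 18),
                    Ip = c(6, 34, 22))
    for (nm in names(origins)) {
      for (k in 1:8) {
        coords[sprintf("%s%02d", nm, k), ] <- origins[[nm]] + c(4.5 * (k - 1), 0, 0)
      }
    }
    list(fmt_string = "SEEG;Am[1x8];Ah[1x8];Ap[1x8];Ip[1x8]",
         fmt = fmt, coords = coords)
  }
}

demo_sphere_mask <- function(center, radius, n = 24L, voxel_mm = 2) {
  ax <- (seq_len(n) - 1) * voxel_mm
  grid <- expand.grid(x = ax, y = ax, z = ax)
  inside <- with(grid, (x - center[1])^2 + (y - center[2])^2 +
                   (z - center[3])^2 <= radius^2)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  resection_mask(array(inside, dim = c(n, n, n)), affine)
}

demo_longterm_subject <- function(i, resp_id, identity, root, kind) {
  layout <- demo_longterm_layout(kind)
  implant <- as.Date("2012-09-03") + i * 23
  mask <- demo_sphere_mask(center = c(18, 20, 16) + (i %% 3), radius = 11)
  labels <- classify_3d(rownames(layout$coords), layout$coords, mask)

  runs <- list(
    list(day = 1L, time = "13:15:00", task = "sleep",
         seg = function(fs, n) rbind(
           trc_note(round(0.5 * fs), "Sl_on"),
           trc_note(round(4.0 * fs), "Sl_off"),
           trc_note(round(4.5 * fs), "Sz_on;C05;C06"),
           trc_note(round(5.5 * fs), "Sz_off;C05;C06"))),
    list(day = 2L, time = "09:30:00", task = "rest",
         seg = function(fs, n) rbind(
           trc_note(0L, "Task;rest"),
           trc_note(round(1.0 * fs), "Sl_on"),
           trc_note(round(2.0 * fs), "Sl_off"),
           trc_note(round(3.0 * fs), "Sz_on"),
           trc_note(round(4.5 * fs), "Sz_off")))
  )
  if (kind == "seeg") {
    runs[[1]]$seg <- function(fs, n) rbind(
      trc_note(round(0.5 * fs), "Sl_on"),
      trc_note(round(4.0 * fs), "Sl_off"),
      trc_note(round(4.5 * fs), "Sz_on;Am03;Am04"),
      trc_note(round(5.5 * fs), "Sz_off;Am03;Am04"),
      trc_note(0L, "Screw;Am08"))
  }

  for (rn in runs) {
    fs <- 512L
    rec_start <- as.POSIXct(paste(implant + rn$day, rn$time), tz = "UTC")
    status_note <- trc_note(0L, sprintf("Bad;%s", rownames(layout$coords)[2]))
    # the full layout string exceeds the 40-char note field; split with the
    # ";"-continuation convention
    fmt_notes <- if (nchar(layout$fmt_string) > 40) {
      cut <- max(gregexpr(";", substr(layout$fmt_string, 1, 40))[[1]])
      rbind(trc_note(0L, substr(layout$fmt_string, 1, cut - 1)),
            trc_note(0L, substr(layout$fmt_string, cut,
                                nchar(layout$fmt_string))))
    } else trc_note(0L, layout$fmt_string)
    notes <- rbind(fmt_notes, status_note, rn$seg(fs, fs * 6))
    spec <- signal_spec(
      labels = rownames(layout$coords), rate = fs, duration_s = 6,
      noise_sd = 7, spike_times = c(1.5, 3.1, 4.8),
      patient = patient_header(identity$surname, identity$given,
                               22, 11, identity$birth_year),
      recording_start = rec_start, notes = notes)
    rec <- synthesize_recording(spec, seed = i * 2000 + rn$day)
    anon <- pseudo_anonymize(rec, resp_id,
                             denylist = c(identity$surname, identity$given))
    stopifnot(nrow(anon$report$residual_findings) == 0)
    parsed <- parse_annotations(anon$recording$notes, n_samples(anon$recording))
    run_label <- longterm_run_label(implant, rec_start)
    entities <- longterm_entities(resp_id, "1", rn$task, run_label)

    src_dir <- file.path(tempdir(), "ieegcurate-demo-src")
    dir.create(src_dir, showWarnings = FALSE)
    trc_path <- file.path(src_dir, paste0(entity_stem(entities), ".TRC"))
    write_trc(anon$recording, trc_path)

    assemble_run(anon$recording, parsed, labels, entities, root,
                 reference_date = implant,
                 subject_info = list(
                   sex = identity$sex,
                   age = as.integer(format(implant, "%Y")) - identity$birth_year),
                 coords = layout$coords,
                 source_files = trc_path,
                 dataset_name = "Synthetic long-term iEEG demonstration study")
  }
  invisible(NULL)
}

#' Generate a synthetic two-root demonstration study
#'
#' Builds an intraoperative ("acute") and a long-term iEEG-BIDS dataset
#' populated entirely with synthetic recordings, annotations, identities and
#' resection geometry.  Acute subjects get 2-9 situations including at least
#' one pre- and one post-resection stage; long-term subjects get one session
#' with runs on two monitoring days, each containing sleep and seizure
#' events, with a 2-grid/2-strip (ECoG) or multi-depth (SEEG) layout and a
#' spherical 3D resection mask.  Deterministic for a fixed spec.
#'
#' @param spec A [demo_study_spec()].
#' @param out_dir Directory receiving `acute/` and `longterm/` roots.
#' @return List with `$acute_root`, `$longterm_root`, `$registry` and
#'   `$denylist` (all synthetic identity tokens, for audit).
#' @export
generate_demo_study <- function(spec, out_dir) {
  stopifnot(inherits(spec, "demo_study_spec"))
  acute_root <- file.path(out_dir, "acute")
  longterm_root <- file.path(out_dir, "longterm")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ensure_dataset_root(acute_root, "Synthetic acute iEEG demonstration study")
  ensure_dataset_root(longterm_root,
                      "Synthetic long-term iEEG demonstration study")

  reg <- id_registry()
  denylist <- character(0)
  with_preserved_seed(spec$seed, {
    idx <- 0L
    for (k in seq_len(spec$n_acute)) {
      idx <- idx + 1L
      identity <- demo_identity(idx)
      alloc <- allocate_resp_id(reg, identity$hospital_id,
                                created = "1900-01-01T00:00:00")
      reg <- alloc$registry
      denylist <- c(denylist, identity$surname, identity$given)
      demo_acute_subject(idx, alloc$resp_id, identity, acute_root, denylist)
    }
    for (kind in c("ecog", "seeg")) {
      n <- if (kind == "ecog") spec$n_longterm_ecog else spec$n_longterm_seeg
      for (k in seq_len(n)) {
        idx <- idx + 1L
        identity <- demo_identity(idx)
        alloc <- allocate_resp_id(reg, identity$hospital_id,
                                  created = "1900-01-01T00:00:00")
        reg <- alloc$registry
        denylist <- c(denylist, identity$surname, identity$given)
        demo_longterm_subject(idx, alloc$resp_id, identity, longterm_root, kind)
      }
    }
  })
  list(acute_root = acute_root, longterm_root = longterm_root,
       registry = reg, denylist = unique(denylist))
}

#' Audit a dataset tree for identity leakage
#'
#' Recursive byte scan of every file under `root` for any denylist token
#' (case-insensitive).
#'
#' @param root Directory to scan.
#' @param denylist Character vector of forbidden tokens.
#' @return `data.frame` (`path`, `token`) of findings; zero rows when clean.
#' @export
audit_identity_leaks <- function(root, denylist) {
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  out <- data.frame(path = character(0), token = character(0),
                    stringsAsFactors = FALSE)
  pats <- tolower(denylist)
  for (f in files) {
    bytes <- readBin(f, "raw", file.info(f)$size)
    txt <- rawToChar(bytes[bytes != as.raw(0)])
    txt <- tolower(iconv(txt, from = "latin1", to = "ASCII", sub = " "))
    for (k in seq_along(pats)) {
      if (grepl(pats[k], txt, fixed = TRUE)) {
        out <- rbind(out, data.frame(path = f, token = denylist[k],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}
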