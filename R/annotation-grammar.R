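# ---------------------------------------------------------------------------
# Annotation grammar: the in-file note syntax clinicians use to enrich TRC
# recordings with the metadata a BIDS conversion needs.  Constructs:
#
#   Format;Gr[4x5]                electrode layout declaration (grid default)
#   ECoG;C[4x8];strip;IHa[1x8]    layout with explicit electrode-type switch
#   SEEG;Am[1x12]                 depth-electrode layout (depth default)
#   Bad;Gr07;Gr12                 channel status marks
#   Silicon;... / Screw;...       more status kinds
#   Sl_on / Sl_off                paired segment markers (sleep here)
#   Sz_on;C05;C06                 markers may carry a channel list
#   Task;SPESclin                 explicit task declaration
#
# Anything else is preserved verbatim as "unparsed": parsing is total and
# never raises on free-text surgeon comments.
#
# Notes are capped at 40 characters by the recording format; a statement
# longer than that is split into continuation notes beginning with ";" at
# the same sample index, which parse_annotations() rejoins.
# ---------------------------------------------------------------------------

SEGMENT_CODES <- c("Sl", "Sz", "Art", "Good", "Rest", "SPES", "Mtr", "Lang",
                   "SSEP")

# long names used as trial_type in events.tsv
SEGMENT_LONG_NAMES <- c(Sl = "sleep", Sz = "seizure", Art = "artefact",
                        Good = "good_segment", Rest = "rest",
                        SPES = "electrical_stimulation", Mtr = "motor_task",
                        Lang = "language_task", SSEP = "ssep")

# segment code -> BIDS task label inference (explicit Task; overrides)
SEGMENT_TASK_MAP <- c(Sl = "sleep", SPES = "SPESclin", Mtr = "motor",
                      Lang = "language", SSEP = "SSEP", Sz = "seizure")

STATUS_KINDS <- c(Bad = "bad", Silicon = "silicon", Screw = "screw")

GROUP_TOKEN_RE <- "^\\s*([A-Za-z][A-Za-z0-9]*)\\s*\\[\\s*([0-9]+)\\s*[x×]\\s*([0-9]+)\\s*\\]\\s*$"

#' Electrode group declaration
#'
#' One grid, strip or depth electrode in a layout declaration.  Contact count
#' is `rows * cols`; strips and depth electrodes are one-dimensional
#' (`rows = 1`).
#'
#' @param name Group name (alphanumeric, e.g. `"Gr"`, `"IHa"`).
#' @param rows,cols Contact grid dimensions.
#' @param gtype `"grid"`, `"strip"` or `"depth"`.
#' @return Object of class `electrode_group`.
#' @export
electrode_group <- function(name, rows, cols, gtype = c("grid", "strip", "depth")) {
  gtype <- match.arg(gtype)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("group dimensions must be >= 1: ", name)
  if (gtype %in% c("strip", "depth") && rows != 1L) {
    stop(gtype, " group '", name, "' must have a single row, got ", rows)
  }
  structure(list(name = name, rows = rows, cols = cols, gtype = gtype),
            class = "electrode_group")
}

#' Electrode format declaration
#'
#' @param modality_token `"Format"`, `"ECoG"` or `"SEEG"` — the head token of
#'   the declaration string.
#' @param groups List of [electrode_group()]s with unique names.
#' @return Object of class `format_spec`.
#' @export
format_spec <- function(modality_token, groups) {
  stopifnot(modality_token %in% c("Format", "ECoG", "SEEG"))
  nm <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate electrode group name: ", nm[duplicated(nm)][1])
  }
  structure(list(modality_token = modality_token, groups = groups),
            class = "format_spec")
}

#' Parse an electrode format string
#'
#' Splits on `";"`.  Tokens of the shape `Name[RxC]` (separator `"x"` or the
#' multiplication sign, spaces allowed) declare a group; the bare keywords
#' `grid`, `strip`, `depth` switch the type assigned to subsequent groups.
#' The default type is grid after a `Format;`/`ECoG;` head and depth after
#' `SEEG;`.
#'
#' @param text The declaration string, beginning with `Format;`, `ECoG;` or
#'   `SEEG;`.
#' @return A [format_spec()].
#' @export
#' @examples
#' parse_format("Format;Gr[4 x 5]")
parse_format <- function(text) {
  tokens <- strsplit(text, ";", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  head <- tokens[1]
  if (!head %in% c("Format", "ECoG", "SEEG")) {
    stop("not a format declaration (must begin with Format;, ECoG; or SEEG;): ",
         text)
  }
  gtype <- if (head == "SEEG") "depth" else "grid"
  groups <- list()
  for (tok in tokens[-1]) {
    if (tok == "") next
    if (tolower(tok) %in% c("grid", "strip", "depth")) {
      gtype <- tolower(tok)
      next
    }
    m <- regmatches(tok, regexec(GROUP_TOKEN_RE, tok))[[1]]
    if (length(m) == 0) stop("malformed electrode dimension token: '", tok, "'")
    groups <- c(groups, list(electrode_group(m[2], m[3], m[4], gtype)))
  }
  format_spec(head, groups)
}

#' Total contact count of a format
#' @param spec A [format_spec()].
#' @return Integer, sum of `rows * cols` over the groups.
#' @export
contact_count <- function(spec) {
  stopifnot(inherits(spec, "format_spec"))
  sum(vapply(spec$groups, function(g) g$rows * g$cols, integer(1)))
}

#' Contact labels implied by a format
#'
#' Contacts are numbered row-major and zero-padded to two digits, matching
#' the labels printed on clinical photos (`Gr01` ... `Gr20`).
#' @param spec A [format_spec()].
#' @export
contact_labels <- function(spec) {
  unlist(lapply(spec$groups, function(g) {
    sprintf("%s%02d", g$name, seq_len(g$rows * g$cols))
  }), use.names = FALSE)
}

#' Canonical serialization of a format
#'
#' Deterministic normalization of a declaration: head token, groups in their
#' original order, `"x"` dimension separator, no spaces, and a type keyword
#' inserted only where the electrode type changes from the running default.
#' `parse_format(canonical_format_string(s))` reproduces `s`.
#'
#' @param spec A [format_spec()].
#' @return The canonical declaration string.
#' @export
canonical_format_string <- function(spec) {
  stopifnot(inherits(spec, "format_spec"))
  current <- if (spec$modality_token == "SEEG") "depth" else "grid"
  parts <- spec$modality_token
  for (g in spec$groups) {
    if (g$gtype != current) {
      parts <- c(parts, g$gtype)
      current <- g$gtype
    }
    parts <- c(parts, sprintf("%s[%dx%d]", g$name, g$rows, g$cols))
  }
  paste(parts, collapse = ";")
}

#' Classify one TRC note against the annotation grammar
#'
#' Total classification by leading token: format declarations, channel status
#' marks (`Bad`/`Silicon`/`Screw`), segment on/off markers, `Task;`
#' declarations; everything else is returned as `unparsed`, never an error.
#'
#' @param sample_index 0-based note position.
#' @param text Note text.
#' @param extra_codes Additional segment codes accepted beyond the built-in
#'   vocabulary (the grammar is extensible).
#' @return A list with `$kind` in
#'   `{"format","status","segment","task","unparsed"}` plus kind-specific
#'   fields.
#' @export
parse_note <- function(sample_index, text, extra_codes = character(0)) {
  codes <- c(SEGMENT_CODES, extra_codes)
  txt <- trimws(text)
  head <- sub("[;_].*$", "", txt)

  if (head %in% c("Format", "ECoG", "SEEG") && grepl(";", txt, fixed = TRUE)) {
    fs <- try(parse_format(txt), silent = TRUE)
    if (!inherits(fs, "try-error")) {
      return(list(kind = "format", format = fs, sample_index = sample_index,
                  text = text))
    }
    return(list(kind = "unparsed", sample_index = sample_index, text = text))
  }

  if (head %in% names(STATUS_KINDS)) {
    chans <- strsplit(sub("^[^;]*;", "", txt), "[;,]")[[1]]
    chans <- trimws(chans[trimws(chans) != ""])
    if (length(chans)) {
      return(list(kind = "status", status = STATUS_KINDS[[head]],
                  channels = chans, sample_index = sample_index, text = text))
    }
    return(list(kind = "unparsed", sample_index = sample_index, text = text))
  }

  m <- regmatches(txt, regexec("^([A-Za-z][A-Za-z0-9]*)_(on|off)(;(.*))?$", txt))[[1]]
  if (length(m) && m[2] %in% codes) {
    chans <- if (m[5] != "" || m[4] != "") {
      cc <- strsplit(m[5], "[;,]")[[1]]
      trimws(cc[trimws(cc) != ""])
    } else character(0)
    return(list(kind = "segment", code = m[2], polarity = m[3],
                channels = chans, sample_index = sample_index, text = text))
  }

  if (grepl("^Task;", txt)) {
    lab <- trimws(sub("^Task;", "", txt))
    if (lab != "") {
      return(list(kind = "task", task = lab, sample_index = sample_index,
                  text = text))
    }
  }

  list(kind = "unparsed", sample_index = sample_index, text = text)
}

#' Pair segment on/off markers into event segments
#'
#' Each `_on` mark pairs with the next `_off` mark of the same code and
#' identical channel set.  Different codes may interleave freely; the same
#' code may not nest.  An `_on` with no matching `_off` is closed at the end
#' of the recording with a warning.
#'
#' @param marks List of segment marks from [parse_note()], in ascending
#'   `sample_index` order.
#' @param n_samples Recording length in samples (closes dangling segments).
#' @return `data.frame` with columns `code`, `onset_sample`, `offset_sample`,
#'   `channels` (`";"`-joined, `""` for whole-recording marks).
#' @export
pair_segments <- function(marks, n_samples) {
  open <- list()  # key = code|channels -> onset sample
  out <- list()
  key_of <- function(mk) paste0(mk$code, "|", paste(sort(mk$channels), collapse = ";"))
  for (mk in marks) {
    k <- key_of(mk)
    if (mk$polarity == "on") {
      if (!is.null(open[[k]])) {
        stop("nested '", mk$code, "_on' at sample ", mk$sample_index,
             " while a segment of the same code is open")
      }
      open[[k]] <- mk
    } else {
      if (is.null(open[[k]])) {
        stop("'", mk$code, "_off' at sample ", mk$sample_index,
             " has no open '", mk$code, "_on'")
      }
      on_mk <- open[[k]]
      open[[k]] <- NULL
      out <- c(out, list(data.frame(
        code = mk$code, onset_sample = on_mk$sample_index,
        offset_sample = mk$sample_index,
        channels = paste(on_mk$channels, collapse = ";"),
        stringsAsFactors = FALSE)))
    }
  }
  for (k in names(open)) {
    mk <- open[[k]]
    warning("'", mk$code, "_on' at sample ", mk$sample_index,
            " has no matching off mark; closed at end of recording")
    out <- c(out, list(data.frame(
      code = mk$code, onset_sample = mk$sample_index,
      offset_sample = n_samples,
      channels = paste(mk$channels, collapse = ";"), stringsAsFactors = FALSE)))
  }
  if (!length(out)) {
    return(data.frame(code = character(0), onset_sample = integer(0),
                      offset_sample = integer(0), channels = character(0),
                      stringsAsFactors = FALSE))
  }
  segs <- do.call(rbind, out)
  segs <- segs[order(segs$onset_sample, segs$code), , drop = FALSE]
  bad <- segs$onset_sample >= segs$offset_sample
  if (any(bad)) stop("segment with onset >= offset for code ", segs$code[bad][1])
  rownames(segs) <- NULL
  segs
}

#' Parse all notes of a recording
#'
#' Runs [parse_note()] over a note table and [pair_segments()] over the
#' resulting segment marks.  Every input note lands in exactly one of the
#' output categories; nothing is dropped and nothing raises.
#'
#' @param notes Note table (`sample_index`, `text`), e.g. `rec$notes`.
#' @param n_samples Recording length in samples.
#' @param extra_codes Passed to [parse_note()].
#' @return Object of class `parsed_annotations`: `$format` (a
#'   [format_spec()] or `NULL`), `$statuses` (data.frame kind/channel/sample),
#'   `$segments` (from [pair_segments()]), `$task` (label or `NULL`),
#'   `$unparsed` (note table).
#' @export
parse_annotations <- function(notes, n_samples, extra_codes = character(0)) {
  notes <- as.data.frame(notes)
  notes <- notes[order(notes$sample_index), , drop = FALSE]
  # note capacity is 40 characters; a statement longer than that is split by
  # the annotator into continuation notes beginning with ";" at the same
  # sample.  Rejoin before classification.
  if (nrow(notes) > 1) {
    keep <- rep(TRUE, nrow(notes))
    last <- 1L
    for (i in 2:nrow(notes)) {
      if (startsWith(notes$text[i], ";") &&
          notes$sample_index[i] == notes$sample_index[last]) {
        notes$text[last] <- paste0(notes$text[last], notes$text[i])
        keep[i] <- FALSE
      } else {
        last <- i
      }
    }
    notes <- notes[keep, , drop = FALSE]
  }
  format <- NULL; task <- NULL
  statuses <- data.frame(kind = character(0), channel = character(0),
                         sample_index = integer(0), stringsAsFactors = FALSE)
  marks <- list()
  unparsed <- empty_notes()
  for (i in seq_len(nrow(notes))) {
    st <- parse_note(notes$sample_index[i], notes$text[i], extra_codes)
    switch(st$kind,
      format = {
        if (!is.null(format)) {
          warning("multiple format declarations; keeping the first")
        } else format <- st$format
      },
      status = {
        statuses <- rbind(statuses, data.frame(
          kind = st$status, channel = st$channels,
          sample_index = st$sample_index, stringsAsFactors = FALSE))
      },
      segment = marks <- c(marks, list(st)),
      task = {
        if (!is.null(task)) warning("multiple Task declarations; keeping the first")
        else task <- st$task
      },
      unparsed = unparsed <- rbind(unparsed, notes[i, , drop = FALSE])
    )
  }
  segments <- pair_segments(marks, n_samples)
  structure(list(format = format, statuses = statuses, segments = segments,
                 task = task, unparsed = unparsed),
            class = "parsed_annotations")
}

#' Infer the BIDS task label from parsed annotations
#'
#' An explicit `Task;` declaration wins; otherwise the dominant segment code
#' with a task mapping (sleep, SPESclin, motor, language, SSEP, seizure)
#' decides; a recording with none of these is `"rest"`.
#'
#' @param parsed A [parse_annotations()] result.
#' @return Task label string.
#' @export
infer_task <- function(parsed) {
  if (!is.null(parsed$task)) return(parsed$task)
  segs <- parsed$segments
  mapped <- segs$code[segs$code %in% names(SEGMENT_TASK_MAP)]
  if (!length(mapped)) return("rest")
  # dominant code = the one covering the most samples
  cov <- tapply(segs$offset_sample - segs$onset_sample, segs$code, sum)
  cov <- cov[names(cov) %in% names(SEGMENT_TASK_MAP)]
  SEGMENT_TASK_MAP[[names(cov)[which.max(cov)]]]
}
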