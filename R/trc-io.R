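# ---------------------------------------------------------------------------
# Micromed-style TRC dialect ("System Plus" header type 4 lineage).
#
# All multi-byte integers are little-endian.  The layout models the fields a
# BIDS conversion needs (patient identity, acquisition start, channel scaling,
# in-file notes); everything else a real acquisition system might append is
# carried as one opaque byte block so that read -> write round-trips are
# byte-identical.
#
#   offset  size  field
#   0       32    magic "MICROMED-STYLE TRC"   (space padded)
#   32      1     header version (must be 4)
#   33..63        reserved (zero)
#   64      22    patient surname   (space padded)
#   86      20    patient given name
#   106     1     birth day
#   107     1     birth month
#   108     2     birth year (full calendar year, uint16)
#   110     1     recording day
#   111     1     recording month
#   112     2     recording year
#   114     1,1,1 recording hour, minute, second
#   117     1     pad
#   118     2     number of channels (uint16)
#   120     2     sampling rate in Hz (uint16, one rate per file)
#   122     2     bytes per sample (must be 2)
#   124     4     number of samples per channel (uint32)
#   128     4     free-text area offset
#   132     4     note area offset
#   136     4     opaque area offset
#   140     4     sample data offset
#   144..255      reserved (zero)
#   256     64*n  channel descriptors (see below)
#
# Channel descriptor (64 bytes):
#   0   12  label (space padded)
#   12  1   unit code (0 = uV, 1 = mV)
#   13  3   pad
#   16  4   logic_min   (int32)
#   20  4   logic_max   (int32)
#   24  4   logic_ground(int32)
#   28  4   pad
#   32  8   phys_min (double, physical units)
#   40  8   phys_max (double)
#   48..63  reserved (zero)
#
# Free-text area: uint16 field count; per field uint16 id, uint16 byte
# length, raw bytes.  Note area: uint32 note count; per note uint32 sample
# index, 40-byte space-padded text.  Opaque area: uint32 length, raw bytes.
# Sample area: uint16 samples, multiplexed (all channels for sample 1, then
# sample 2, ...), unsigned with the logic_ground offset.
# ---------------------------------------------------------------------------

TRC_MAGIC <- "MICROMED-STYLE TRC"
TRC_HEADER_SIZE <- 256L
TRC_CHAN_DESC_SIZE <- 64L
TRC_NOTE_TEXT_SIZE <- 40L
TRC_SUPPORTED_RATES <- c(256L, 512L, 1024L, 2048L)

#' Patient header of a TRC recording
#'
#' Identity block stored in the patient area of the TRC dialect: name fields,
#' date of birth, and the free-text fields used by acquisition software for
#' montage names, comments and clinical history.
#'
#' @param surname Surname, at most 22 characters.
#' @param given_name Given name, at most 20 characters.
#' @param birth_day,birth_month,birth_year Date of birth; must form a valid
#'   calendar date.
#' @param free_text_fields `data.frame` with integer column `id` (unique) and
#'   character column `text`; order is preserved in the file.
#' @return An object of class `patient_header`.
#' @export
patient_header <- function(surname, given_name = "",
                           birth_day = 1L, birth_month = 1L, birth_year = 1970L,
                           free_text_fields = empty_free_text()) {
  if (nchar(surname) > 22L) stop("surname exceeds 22 characters: ", surname)
  if (nchar(given_name) > 20L) stop("given_name exceeds 20 characters")
  birth_day <- as.integer(birth_day)
  birth_month <- as.integer(birth_month)
  birth_year <- as.integer(birth_year)
  d <- try(as.Date(sprintf("%04d-%02d-%02d", birth_year, birth_month, birth_day)),
           silent = TRUE)
  if (inherits(d, "try-error") || is.na(d)) {
    stop(sprintf("birth date %d-%d-%d is not a valid calendar date",
                 birth_day, birth_month, birth_year))
  }
  free_text_fields <- as.data.frame(free_text_fields)
  stopifnot(all(c("id", "text") %in% names(free_text_fields)))
  if (anyDuplicated(free_text_fields$id)) stop("free_text_fields ids must be unique")
  structure(list(surname = surname, given_name = given_name,
                 birth_day = birth_day, birth_month = birth_month,
                 birth_year = birth_year,
                 free_text_fields = free_text_fields),
            class = "patient_header")
}

#' @rdname patient_header
#' @export
empty_free_text <- function() data.frame(id = integer(0), text = character(0),
                                         stringsAsFactors = FALSE)

#' Channel descriptor table
#'
#' Builds the per-channel scaling table of a TRC recording.  The physical
#' value of a raw sample is reconstructed as
#' `phys = (raw - logic_ground) / (logic_max - logic_min + 1) * (phys_max - phys_min)`.
#'
#' @param labels Character vector of channel labels (e.g. `"Gr01"`).
#' @param physical_unit `"uV"` or `"mV"`, recycled across channels.
#' @param logic_min,logic_max,logic_ground Integer logic range; defaults span
#'   the full unsigned 16-bit range with mid-range ground.
#' @param phys_min,phys_max Physical range in `physical_unit`.
#' @param sampling_rate Sampling rate in Hz; a single rate for all channels.
#' @return `data.frame` with one row per channel.
#' @export
channel_table <- function(labels, physical_unit = "uV",
                          logic_min = 0L, logic_max = 65535L,
                          logic_ground = 32768L,
                          phys_min = -3276.8, phys_max = 3276.8,
                          sampling_rate = 512L) {
  if (any(nchar(labels) > 12L)) stop("channel labels are limited to 12 characters")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(physical_unit %in% c("uV", "mV"))) stop("physical_unit must be uV or mV")
  ch <- data.frame(label = as.character(labels),
                   physical_unit = physical_unit,
                   logic_min = as.integer(logic_min),
                   logic_max = as.integer(logic_max),
                   logic_ground = as.integer(logic_ground),
                   phys_min = as.numeric(phys_min),
                   phys_max = as.numeric(phys_max),
                   sampling_rate = as.integer(sampling_rate),
                   stringsAsFactors = FALSE)
  bad <- ch$logic_min >= ch$logic_max | ch$phys_min >= ch$phys_max
  if (any(bad)) stop("logic_min < logic_max and phys_min < phys_max required for: ",
                     paste(ch$label[bad], collapse = ", "))
  if (length(unique(ch$sampling_rate)) != 1L) {
    stop("all channels in one recording must share a single sampling rate")
  }
  ch
}

#' Note (annotation) attached to a TRC recording
#'
#' @param sample_index 0-based sample position of the note.
#' @param text Annotation text, at most 40 characters.
#' @return `data.frame` row; bind with `rbind()` to build a note table.
#' @export
trc_note <- function(sample_index, text) {
  if (any(nchar(text) > TRC_NOTE_TEXT_SIZE)) {
    stop("note text exceeds ", TRC_NOTE_TEXT_SIZE, " characters: ",
         text[which(nchar(text) > TRC_NOTE_TEXT_SIZE)[1]])
  }
  data.frame(sample_index = as.integer(sample_index), text = as.character(text),
             stringsAsFactors = FALSE)
}

#' @export
empty_notes <- function() data.frame(sample_index = integer(0), text = character(0),
                                     stringsAsFactors = FALSE)

#' Multichannel TRC recording
#'
#' The in-memory unit of clinical source data: a patient header, acquisition
#' start, channel scaling table, raw 16-bit sample matrix and in-file notes.
#'
#' @param patient A [patient_header()].
#' @param recording_start `POSIXct` acquisition start (stored as local
#'   calendar date and wall time).
#' @param channels A [channel_table()].
#' @param samples Integer matrix, channels x time, raw values within each
#'   channel's logic range.
#' @param notes Note table from [trc_note()] rows.
#' @param opaque Raw vector carried verbatim for unmodeled header areas.
#' @return Object of class `trc_recording`.
#' @export
trc_recording <- function(patient, recording_start, channels, samples,
                          notes = empty_notes(), opaque = raw(0)) {
  stopifnot(inherits(patient, "patient_header"), is.matrix(samples))
  samples <- matrix(as.integer(samples), nrow = nrow(samples))
  if (nrow(samples) != nrow(channels)) {
    stop("samples has ", nrow(samples), " rows but channels declares ",
         nrow(channels))
  }
  out_of_range <- samples < rep(channels$logic_min, ncol(samples)) |
    samples > rep(channels$logic_max, ncol(samples))
  if (any(out_of_range)) stop("raw samples outside the declared logic range")
  notes <- as.data.frame(notes)
  if (nrow(notes) && any(notes$sample_index >= ncol(samples))) {
    stop("note sample_index beyond the end of the recording")
  }
  if (nrow(notes) && any(nchar(notes$text) > TRC_NOTE_TEXT_SIZE)) {
    stop("note text exceeds ", TRC_NOTE_TEXT_SIZE, " characters")
  }
  rec <- structure(list(patient = patient,
                        recording_start = as.POSIXct(recording_start, tz = "UTC"),
                        channels = channels, samples = samples,
                        notes = notes, opaque = as.raw(opaque)),
                   class = "trc_recording")
  rec
}

#' @export
print.trc_recording <- function(x, ...) {
  cat(sprintf("<trc_recording> %d ch x %d samples @ %d Hz (%.1f s), %d notes\n",
              nrow(x$samples), ncol(x$samples), x$channels$sampling_rate[1],
              ncol(x$samples) / x$channels$sampling_rate[1], nrow(x$notes)))
  invisible(x)
}

#' Number of samples / sampling rate / duration helpers
#' @param rec A `trc_recording`.
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname n_samples
#' @export
sampling_rate <- function(rec) rec$channels$sampling_rate[1]

#' @rdname n_samples
#' @export
recording_duration <- function(rec) ncol(rec$samples) / sampling_rate(rec)

#' Physical-value reconstruction
#'
#' Applies the per-channel linear scaling to the raw sample matrix.
#'
#' @param rec A `trc_recording`.
#' @return Numeric matrix, channels x time, in each channel's physical unit.
#' @export
trc_physical <- function(rec) {
  ch <- rec$channels
  span <- ch$logic_max - ch$logic_min + 1
  (rec$samples - ch$logic_ground) / span * (ch$phys_max - ch$phys_min)
}

#' Physical least significant bit per channel
#' @param channels A [channel_table()].
#' @export
physical_lsb <- function(channels) {
  (channels$phys_max - channels$phys_min) /
    (channels$logic_max - channels$logic_min + 1)
}

# quantize a channels x time physical matrix to raw values; errors on clipping
trc_quantize <- function(phys, channels) {
  lsb <- physical_lsb(channels)
  raw <- round(phys / lsb) + channels$logic_ground
  clip <- raw < channels$logic_min | raw > channels$logic_max
  if (any(clip)) {
    stop("physical values do not fit the 16-bit logic range without clipping (",
         sum(clip), " samples)")
  }
  matrix(as.integer(raw), nrow = nrow(phys))
}

# -- binary primitives -------------------------------------------------------

pad_chars <- function(text, width) {
  b <- charToRaw(text)
  if (length(b) > width) stop("string wider than field: ", text)
  c(b, rep(charToRaw(" "), width - length(b)))
}

unpad_chars <- function(bytes) {
  bytes[bytes == as.raw(0)] <- charToRaw(" ")
  sub(" +$", "", rawToChar(bytes))
}

u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
i32_raw <- u32_raw
dbl_raw <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

read_u8  <- function(con) readBin(con, "integer", size = 1, signed = FALSE)
read_u16 <- function(con, n = 1) readBin(con, "integer", n, size = 2,
                                         signed = FALSE, endian = "little")
read_u32 <- function(con, n = 1) readBin(con, "integer", n, size = 4,
                                         endian = "little")
read_dbl <- function(con, n = 1) readBin(con, "double", n, size = 8,
                                         endian = "little")

# -- writer ------------------------------------------------------------------

serialize_trc <- function(rec) {
  ch <- rec$channels
  n_ch <- nrow(ch)
  n_samp <- ncol(rec$samples)
  if (!ch$sampling_rate[1] %in% TRC_SUPPORTED_RATES) {
    stop("unsupported sampling rate ", ch$sampling_rate[1], " Hz; supported: ",
         paste(TRC_SUPPORTED_RATES, collapse = ", "))
  }
  if (nrow(rec$notes) && any(nchar(rec$notes$text) > TRC_NOTE_TEXT_SIZE)) {
    bad <- rec$notes$text[nchar(rec$notes$text) > TRC_NOTE_TEXT_SIZE][1]
    stop("note text exceeds ", TRC_NOTE_TEXT_SIZE, " characters: ", bad)
  }

  ft <- rec$patient$free_text_fields
  ft_area <- c(u16_raw(nrow(ft)),
               unlist(lapply(seq_len(nrow(ft)), function(i) {
                 b <- charToRaw(ft$text[i])
                 c(u16_raw(ft$id[i]), u16_raw(length(b)), b)
               })))
  if (is.null(ft_area)) ft_area <- u16_raw(0L)

  # stable sort: notes at the same sample keep insertion order (annotation
  # continuations depend on it)
  notes <- rec$notes[order(rec$notes$sample_index), , drop = FALSE]
  note_area <- c(u32_raw(nrow(notes)),
                 unlist(lapply(seq_len(nrow(notes)), function(i) {
                   c(u32_raw(notes$sample_index[i]),
                     pad_chars(notes$text[i], TRC_NOTE_TEXT_SIZE))
                 })))
  opaque_area <- c(u32_raw(length(rec$opaque)), rec$opaque)

  desc_off <- TRC_HEADER_SIZE
  ft_off <- desc_off + n_ch * TRC_CHAN_DESC_SIZE
  note_off <- ft_off + length(ft_area)
  opq_off <- note_off + length(note_area)
  data_off <- opq_off + length(opaque_area)

  p <- rec$patient
  st <- as.POSIXlt(rec$recording_start, tz = "UTC")
  header <- raw(TRC_HEADER_SIZE)
  put <- function(h, off, bytes) { h[(off + 1):(off + length(bytes))] <- bytes; h }
  header <- put(header, 0L, pad_chars(TRC_MAGIC, 32L))
  header <- put(header, 32L, as.raw(4L))
  header <- put(header, 64L, pad_chars(p$surname, 22L))
  header <- put(header, 86L, pad_chars(p$given_name, 20L))
  header <- put(header, 106L, as.raw(c(p$birth_day, p$birth_month)))
  header <- put(header, 108L, u16_raw(p$birth_year))
  header <- put(header, 110L, as.raw(c(st$mday, st$mon + 1L)))
  header <- put(header, 112L, u16_raw(st$year + 1900L))
  header <- put(header, 114L, as.raw(c(st$hour, st$min, round(st$sec))))
  header <- put(header, 118L, u16_raw(n_ch))
  header <- put(header, 120L, u16_raw(ch$sampling_rate[1]))
  header <- put(header, 122L, u16_raw(2L))
  header <- put(header, 124L, u32_raw(n_samp))
  header <- put(header, 128L, u32_raw(ft_off))
  header <- put(header, 132L, u32_raw(note_off))
  header <- put(header, 136L, u32_raw(opq_off))
  header <- put(header, 140L, u32_raw(data_off))

  descs <- unlist(lapply(seq_len(n_ch), function(i) {
    d <- raw(TRC_CHAN_DESC_SIZE)
    d <- put(d, 0L, pad_chars(ch$label[i], 12L))
    d <- put(d, 12L, as.raw(match(ch$physical_unit[i], c("uV", "mV")) - 1L))
    d <- put(d, 16L, i32_raw(ch$logic_min[i]))
    d <- put(d, 20L, i32_raw(ch$logic_max[i]))
    d <- put(d, 24L, i32_raw(ch$logic_ground[i]))
    d <- put(d, 32L, dbl_raw(ch$phys_min[i]))
    d <- put(d, 40L, dbl_raw(ch$phys_max[i]))
    d
  }))

  data_area <- u16_raw(as.vector(rec$samples))  # column-major = multiplexed
  c(header, descs, ft_area, note_area, opaque_area, data_area)
}

#' Write a recording in the TRC dialect
#'
#' Serialization is deterministic: the same recording always yields identical
#' bytes, and notes are stored in ascending sample order.
#'
#' @param rec A [trc_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(rec, path) {
  stopifnot(inherits(rec, "trc_recording"))
  writeBin(serialize_trc(rec), path)
  invisible(path)
}

# -- reader ------------------------------------------------------------------

#' Read a recording in the TRC dialect
#'
#' Inverse of [write_trc()]: header fields, channel table, notes, samples and
#' the opaque trailing area are restored exactly, so write -> read -> write is
#' byte-identical.
#'
#' @param path Path to a TRC-dialect file.
#' @return A [trc_recording()].
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- unpad_chars(readBin(con, "raw", 32))
  if (!identical(magic, TRC_MAGIC)) {
    stop("malformed TRC header: magic/title area is '", magic, "'")
  }
  version <- read_u8(con)
  if (version != 4L) stop("unsupported TRC header version ", version,
                          "; this reader targets header type 4")
  readBin(con, "raw", 31)  # reserved
  surname <- unpad_chars(readBin(con, "raw", 22))
  given <- unpad_chars(readBin(con, "raw", 20))
  bday <- read_u8(con); bmon <- read_u8(con); byear <- read_u16(con)
  rday <- read_u8(con); rmon <- read_u8(con); ryear <- read_u16(con)
  rh <- read_u8(con); rm <- read_u8(con); rs <- read_u8(con); read_u8(con)
  n_ch <- read_u16(con)
  rate <- read_u16(con)
  bps <- read_u16(con)
  if (bps != 2L) stop("malformed TRC header: bytes_per_sample is ", bps,
                      " (mixed-rate / non-16-bit variants are not supported)")
  n_samp <- read_u32(con)
  ft_off <- read_u32(con); note_off <- read_u32(con)
  opq_off <- read_u32(con); data_off <- read_u32(con)
  if (!(TRC_HEADER_SIZE <= ft_off && ft_off <= note_off && note_off <= opq_off &&
        opq_off <= data_off)) {
    stop("malformed TRC header: area offsets are not monotonically ordered")
  }
  if (!rate %in% TRC_SUPPORTED_RATES) {
    stop("malformed TRC header: sampling_rate ", rate, " Hz is unsupported")
  }
  readBin(con, "raw", TRC_HEADER_SIZE - 144L)  # reserved tail

  descs <- lapply(seq_len(n_ch), function(i) {
    label <- unpad_chars(readBin(con, "raw", 12))
    unit <- c("uV", "mV")[read_u8(con) + 1L]
    readBin(con, "raw", 3)
    lmin <- read_u32(con); lmax <- read_u32(con); lgnd <- read_u32(con)
    readBin(con, "raw", 4)
    pmin <- read_dbl(con); pmax <- read_dbl(con)
    readBin(con, "raw", 16)
    data.frame(label = label, physical_unit = unit, logic_min = lmin,
               logic_max = lmax, logic_ground = lgnd, phys_min = pmin,
               phys_max = pmax, sampling_rate = rate, stringsAsFactors = FALSE)
  })
  channels <- do.call(rbind, descs)

  n_ft <- read_u16(con)
  ft <- empty_free_text()
  for (i in seq_len(n_ft)) {
    id <- read_u16(con); len <- read_u16(con)
    ft <- rbind(ft, data.frame(id = id,
                               text = rawToChar(readBin(con, "raw", len)),
                               stringsAsFactors = FALSE))
  }

  n_notes <- read_u32(con)
  notes <- empty_notes()
  if (n_notes > 0) {
    notes <- do.call(rbind, lapply(seq_len(n_notes), function(i) {
      s <- read_u32(con)
      txt <- unpad_chars(readBin(con, "raw", TRC_NOTE_TEXT_SIZE))
      data.frame(sample_index = s, text = txt, stringsAsFactors = FALSE)
    }))
  }

  opq_len <- read_u32(con)
  opaque <- readBin(con, "raw", opq_len)

  expected_bytes <- n_ch * n_samp * 2
  actual_bytes <- size - data_off
  if (actual_bytes < expected_bytes) {
    stop(sprintf("truncated TRC sample area: expected %d bytes, found %d",
                 expected_bytes, actual_bytes))
  }
  raw_samples <- read_u16(con, n_ch * n_samp)
  samples <- matrix(raw_samples, nrow = n_ch)

  patient <- patient_header(surname, given, bday, bmon, byear,
                            free_text_fields = ft)
  start <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:%02d",
                              ryear, rmon, rday, rh, rm, rs), tz = "UTC")
  trc_recording(patient, start, channels, samples, notes, opaque)
}

# -- synthesis ---------------------------------------------------------------

#' Specification of a synthetic iEEG recording
#'
#' Describes the signal content that [synthesize_recording()] turns into a
#' `trc_recording`: sinusoidal components common to all channels, Gaussian
#' noise, optional interictal-spike transients and optional burst-suppression
#' alternation (1 s on / 1 s off), as seen under propofol anesthesia.
#'
#' @param labels Channel labels (determines the channel count).
#' @param rate Sampling rate in Hz; one of 256, 512, 1024, 2048.
#' @param duration_s Recording duration in seconds.
#' @param components List of `list(freq, amp, phase)` sinusoids (Hz, uV, rad).
#' @param noise_sd Gaussian noise standard deviation in uV.
#' @param spike_times Times (s) at which a stereotyped 80 uV biphasic
#'   interictal-spike transient is injected on all channels.
#' @param burst_suppression If `TRUE`, the signal alternates 1 s of activity
#'   with 1 s of suppression.
#' @param patient A [patient_header()]; a generic placeholder by default.
#' @param recording_start Acquisition start datetime.
#' @param notes Note table stamped into the file (annotation grammar input).
#' @return Object of class `signal_spec`.
#' @export
signal_spec <- function(labels, rate = 512L, duration_s = 4,
                        components = list(list(freq = 9, amp = 40, phase = 0),
                                          list(freq = 2, amp = 60, phase = 1)),
                        noise_sd = 8, spike_times = numeric(0),
                        burst_suppression = FALSE,
                        patient = patient_header("Doe", "John", 14, 7, 1985),
                        recording_start = as.POSIXct("2010-03-04 10:00:00",
                                                     tz = "UTC"),
                        notes = empty_notes()) {
  rate <- as.integer(rate)
  if (!rate %in% TRC_SUPPORTED_RATES) {
    stop("sampling rate ", rate, " Hz is outside the supported set {",
         paste(TRC_SUPPORTED_RATES, collapse = ", "), "}")
  }
  structure(list(labels = as.character(labels), rate = rate,
                 duration_s = duration_s, components = components,
                 noise_sd = noise_sd, spike_times = spike_times,
                 burst_suppression = burst_suppression, patient = patient,
                 recording_start = as.POSIXct(recording_start, tz = "UTC"),
                 notes = as.data.frame(notes)),
            class = "signal_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize a TRC recording
#'
#' Deterministic for a fixed `(spec, seed)` pair.  The physical signal is
#' quantized into the 16-bit logic range; an error is raised if the requested
#' amplitudes would clip.
#'
#' @param spec A [signal_spec()].
#' @param seed Integer seed controlling noise and spike morphology jitter.
#' @return A [trc_recording()].
#' @export
synthesize_recording <- function(spec, seed) {
  stopifnot(inherits(spec, "signal_spec"))
  n_ch <- length(spec$labels)
  n <- round(spec$duration_s * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate

  base <- rep(0, n)
  for (cmp in spec$components) {
    base <- base + cmp$amp * sin(2 * pi * cmp$freq * t + cmp$phase)
  }
  envelope <- if (spec$burst_suppression) as.numeric(floor(t) %% 2 == 0) else 1

  phys <- with_preserved_seed(seed, {
    m <- matrix(rep(base, each = 1), nrow = n_ch, ncol = n, byrow = TRUE)
    m <- m * rep(1, n_ch)  # identical deterministic component on all channels
    if (spec$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(n_ch * n, sd = spec$noise_sd), nrow = n_ch)
    }
    for (ts in spec$spike_times) {
      idx <- round(ts * spec$rate) + 1L
      wave <- 80 * c(seq(0, 1, length.out = round(0.02 * spec$rate)),
                     seq(1, -0.4, length.out = round(0.03 * spec$rate)),
                     seq(-0.4, 0, length.out = round(0.03 * spec$rate)))
      span <- idx + seq_along(wave) - 1L
      keep <- span <= n
      m[, span[keep]] <- m[, span[keep]] +
        matrix(wave[keep], nrow = n_ch, ncol = sum(keep), byrow = TRUE)
    }
    sweep(m, 2, envelope, `*`)
  })

  channels <- channel_table(spec$labels, sampling_rate = spec$rate)
  samples <- trc_quantize(phys, channels)
  trc_recording(spec$patient, spec$recording_start, channels, samples,
                notes = spec$notes)
}
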