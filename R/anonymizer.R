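# ---------------------------------------------------------------------------
# Pseudo-anonymization: identity is replaced by a RESP#### study code, the
# date of birth truncated to January 1 of the birth year, and free text
# scrubbed of name tokens.  Re-identification capability lives only in a
# restricted registry file kept outside any dataset tree.
# ---------------------------------------------------------------------------

RESP_ID_RE <- "^RESP[0-9]{4}$"

#' Identifier registry
#'
#' Append-only table associating hospital identifiers with RESP study codes
#' (`RESP0001`, `RESP0002`, ...).  Stored as TSV with columns `resp_id`,
#' `hospital_id`, `created`; the file must live outside the BIDS root and be
#' access-restricted, since it is the only re-identification key.
#'
#' @param path Optional TSV path to load; a missing file yields an empty
#'   registry bound to that path.
#' @return Object of class `id_registry`.
#' @export
id_registry <- function(path = NULL) {
  entries <- data.frame(resp_id = character(0), hospital_id = character(0),
                        created = character(0), stringsAsFactors = FALSE)
  if (!is.null(path) && file.exists(path)) {
    entries <- utils::read.delim(path, colClasses = "character")
    stopifnot(all(c("resp_id", "hospital_id", "created") %in% names(entries)))
    if (anyDuplicated(entries$resp_id) || anyDuplicated(entries$hospital_id)) {
      stop("corrupt registry: resp_id/hospital_id must be one-to-one")
    }
    if (!all(grepl(RESP_ID_RE, entries$resp_id))) {
      stop("corrupt registry: malformed resp_id entries")
    }
  }
  structure(list(entries = entries, path = path), class = "id_registry")
}

#' @export
print.id_registry <- function(x, ...) {
  cat(sprintf("<id_registry> %d entries%s\n", nrow(x$entries),
              if (!is.null(x$path)) paste0(" (", x$path, ")") else ""))
  invisible(x)
}

#' Allocate (or look up) a RESP identifier
#'
#' Idempotent per hospital identifier: a patient already registered gets
#' their existing code back; a new patient gets the next unused `RESP####`.
#'
#' @param reg An [id_registry()].
#' @param hospital_id Opaque hospital identifier.
#' @param created Timestamp recorded with a new allocation.
#' @return List with `$resp_id` and the (possibly extended) `$registry`.
#' @export
allocate_resp_id <- function(reg, hospital_id,
                             created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stopifnot(inherits(reg, "id_registry"), is.character(hospital_id),
            nzchar(hospital_id))
  hit <- match(hospital_id, reg$entries$hospital_id)
  if (!is.na(hit)) {
    return(list(resp_id = reg$entries$resp_id[hit], registry = reg))
  }
  used <- as.integer(sub("^RESP", "", reg$entries$resp_id))
  nxt <- if (length(used)) max(used) + 1L else 1L
  if (nxt > 9999L) stop("registry exhausted: all 9999 RESP identifiers allocated")
  resp_id <- sprintf("RESP%04d", nxt)
  reg$entries <- rbind(reg$entries,
                       data.frame(resp_id = resp_id, hospital_id = hospital_id,
                                  created = created, stringsAsFactors = FALSE))
  list(resp_id = resp_id, registry = reg)
}

#' Persist a registry to its TSV file
#' @param reg An [id_registry()].
#' @param path Destination; defaults to the path the registry was bound to.
#' @export
write_registry <- function(reg, path = reg$path) {
  if (is.null(path)) stop("registry has no bound path; supply one")
  utils::write.table(reg$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# case-insensitive whole-token removal; token boundaries are non-alphanumerics
scrub_text <- function(text, denylist) {
  hits <- character(0)
  for (tok in denylist) {
    re <- paste0("(?i)(?<![[:alnum:]])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tok),
                 "(?![[:alnum:]])")
    if (grepl(re, text, perl = TRUE)) {
      hits <- c(hits, tok)
      text <- gsub(re, "", text, perl = TRUE)
    }
  }
  list(text = text, hits = hits)
}

#' Pseudo-anonymize a TRC recording
#'
#' Applies the identity scrub: surname becomes the RESP code, given name is
#' cleared, the date of birth is truncated to January 1 of the birth year
#' (the year itself is kept for age computation), and every free-text field
#' and note is scrubbed of denylist tokens by case-insensitive whole-token
#' matching.  Sample data are never touched.
#'
#' @param rec A [trc_recording()].
#' @param resp_id Study code matching `RESP####`.
#' @param denylist Character vector of name tokens to remove.
#' @return List with `$recording` (scrubbed) and `$report` (a `scrub_report`
#'   with `changed_fields` and `residual_findings` data.frames).
#' @export
pseudo_anonymize <- function(rec, resp_id, denylist = character(0)) {
  stopifnot(inherits(rec, "trc_recording"))
  if (!grepl(RESP_ID_RE, resp_id)) {
    stop("resp_id must match RESP followed by 4 digits, got: ", resp_id)
  }
  changed <- data.frame(field = character(0), action = character(0),
                        stringsAsFactors = FALSE)
  note_change <- function(field, action) {
    changed <<- rbind(changed, data.frame(field = field, action = action,
                                          stringsAsFactors = FALSE))
  }

  p <- rec$patient
  if (!identical(p$surname, resp_id)) note_change("surname", "replaced")
  if (nzchar(p$given_name)) note_change("given_name", "cleared")
  if (p$birth_day != 1L || p$birth_month != 1L) {
    note_change("birth_date", "truncated-date")
  }
  ft <- p$free_text_fields
  for (i in seq_len(nrow(ft))) {
    sc <- scrub_text(ft$text[i], denylist)
    if (length(sc$hits)) {
      ft$text[i] <- sc$text
      note_change(sprintf("free_text_%d", ft$id[i]), "cleared")
    }
  }
  notes <- rec$notes
  for (i in seq_len(nrow(notes))) {
    sc <- scrub_text(notes$text[i], denylist)
    if (length(sc$hits)) {
      notes$text[i] <- sc$text
      note_change(sprintf("note_%d", i), "cleared")
    }
  }

  rec$patient <- patient_header(resp_id, "", 1L, 1L, p$birth_year,
                                free_text_fields = ft)
  rec$notes <- notes
  residual <- verify_scrubbed(rec, denylist)
  report <- structure(list(changed_fields = changed, residual_findings = residual),
                      class = "scrub_report")
  list(recording = rec, report = report)
}

#' Verify that a recording carries no identity
#'
#' Scans the surname (must be RESP-formatted), given name (must be empty),
#' birth day/month (must be 1/1), and all free-text fields and notes for
#' denylist tokens.
#'
#' @param rec A [trc_recording()].
#' @param denylist Name tokens that must not appear anywhere.
#' @return `data.frame` of violations (`field`, `token`); zero rows when
#'   clean.
#' @export
verify_scrubbed <- function(rec, denylist = character(0)) {
  v <- data.frame(field = character(0), token = character(0),
                  stringsAsFactors = FALSE)
  add <- function(field, token) {
    v <<- rbind(v, data.frame(field = field, token = token,
                              stringsAsFactors = FALSE))
  }
  p <- rec$patient
  if (!grepl(RESP_ID_RE, p$surname)) add("surname", p$surname)
  if (nzchar(p$given_name)) add("given_name", p$given_name)
  if (p$birth_day != 1L || p$birth_month != 1L) {
    add("birth_date", sprintf("%02d-%02d", p$birth_day, p$birth_month))
  }
  scan <- function(field, text) {
    for (tok in denylist) {
      re <- paste0("(?i)(?<![[:alnum:]])",
                   gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tok),
                   "(?![[:alnum:]])")
      if (grepl(re, text, perl = TRUE)) add(field, tok)
    }
  }
  ft <- p$free_text_fields
  for (i in seq_len(nrow(ft))) scan(sprintf("free_text_%d", ft$id[i]), ft$text[i])
  for (i in seq_len(nrow(rec$notes))) {
    scan(sprintf("note_%d", i), rec$notes$text[i])
  }
  v
}
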