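test_that("format strings parse to the declared layouts", {
  fs <- parse_format("Format;Gr[4 × 5]")
  expect_length(fs$groups, 1L)
  expect_equal(fs$groups[[1]]$gtype, "grid")
  expect_equal(contact_count(fs), 20L)

  fs2 <- parse_format("ECoG;C[4 × 8];CH[2 × 8];strip;IHa[1 × 8];IHv[1 × 8]")
  types <- vapply(fs2$groups, `[[`, "", "gtype")
  expect_equal(sum(types == "grid"), 2L)
  expect_equal(sum(types == "strip"), 2L)
  expect_equal(contact_count(fs2), 64L)

  fs3 <- parse_format("SEEG;Am[1 x 12]")
  expect_equal(fs3$groups[[1]]$gtype, "depth")
  expect_equal(contact_count(fs3), 12L)
})

test_that("malformed or duplicated format tokens error", {
  expect_error(parse_format("Format;Gr[4x]"), "malformed")
  expect_error(parse_format("Format;Gr[4x5];Gr[2x2]"), "duplicate")
  expect_error(parse_format("Montage;Gr[4x5]"), "must begin")
  expect_error(parse_format("Format;strip;S[2x4]"), "single row")
})

test_that("canonical serialization normalizes and round-trips", {
  s <- "ECoG;C[4 × 8];CH[2 × 8];strip;IHa[1 × 8];IHv[1 × 8]"
  fs <- parse_format(s)
  canon <- canonical_format_string(fs)
  expect_equal(canon, "ECoG;C[4x8];CH[2x8];strip;IHa[1x8];IHv[1x8]")
  expect_equal(canonical_format_string(parse_format(canon)), canon)
  expect_equal(canonical_format_string(parse_format("Format;Gr[4 × 5]")),
               "Format;Gr[4x5]")
  # parse . serialize is the identity on specs
  expect_equal(parse_format(canon), fs)
})

test_that("notes classify by leading token and unknown text falls through", {
  st <- parse_note(0L, "Bad;Gr07;Gr12")
  expect_equal(st$kind, "status")
  expect_equal(st$status, "bad")
  expect_equal(st$channels, c("Gr07", "Gr12"))

  seg <- parse_note(10240L, "Sl_on")
  expect_equal(seg[c("kind", "code", "polarity")],
               list(kind = "segment", code = "Sl", polarity = "on"))
  expect_equal(seg$sample_index, 10240L)

  expect_equal(parse_note(0L, "Screw;Am12")$status, "screw")
  expect_equal(parse_note(0L, "Silicon;C01")$status, "silicon")
  expect_equal(parse_note(5L, "Sz_on;C05,C06")$channels, c("C05", "C06"))
  expect_equal(parse_note(0L, "Task;SPESclin")$task, "SPESclin")
  expect_equal(parse_note(0L, "surgeon comment xyz")$kind, "unparsed")
  expect_equal(parse_note(0L, "Foo_on")$kind, "unparsed")
  expect_equal(parse_note(0L, "Foo_on", extra_codes = "Foo")$kind, "segment")
})

test_that("segment pairing matches on/off of the same code and channel set", {
  mk <- function(code, pol, s, ch = character(0)) {
    list(kind = "segment", code = code, polarity = pol, channels = ch,
         sample_index = s)
  }
  segs <- pair_segments(list(mk("Sl", "on", 1000L), mk("Sl", "off", 3048L)),
                        10000L)
  expect_equal(segs$onset_sample, 1000L)
  expect_equal(segs$offset_sample, 3048L)

  # interleaving across codes is allowed
  segs2 <- pair_segments(list(mk("Sz", "on", 500L), mk("Art", "on", 600L),
                              mk("Art", "off", 700L), mk("Sz", "off", 900L)),
                         10000L)
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$code, c("Sz", "Art"))

  expect_error(pair_segments(list(mk("Sl", "off", 100L)), 1000L), "no open")
  expect_error(pair_segments(list(mk("Sl", "on", 1L), mk("Sl", "on", 2L)),
                             1000L), "nested")
  expect_warning(
    dangling <- pair_segments(list(mk("Sz", "on", 50L)), 200L),
    "closed at end")
  expect_equal(dangling$offset_sample, 200L)
})

test_that("every note lands in exactly one category (totality)", {
  texts <- c("Format;Gr[2x3]", "Bad;Gr01", "Sl_on", "Sl_off",
             "free text", "Task;motor", "Silicon;Gr02", "???", "Rest_on",
             "Rest_off")
  notes <- trc_note(seq_along(texts) * 10L, texts)
  parsed <- parse_annotations(notes, 1000L)
  n_classified <- (!is.null(parsed$format)) + nrow(parsed$statuses) +
    2 * nrow(parsed$segments) + (!is.null(parsed$task)) + nrow(parsed$unparsed)
  expect_equal(n_classified, length(texts))
  expect_equal(nrow(parsed$unparsed), 2L)
  expect_equal(nrow(parsed$segments), 2L)
})

test_that("over-long statements split into ;-continuations rejoin", {
  long <- "ECoG;C[4x8];CH[2x8];strip;IHa[1x8];IHv[1x8]"
  notes <- rbind(trc_note(0L, "ECoG;C[4x8];CH[2x8];strip"),
                 trc_note(0L, ";IHa[1x8];IHv[1x8]"))
  parsed <- parse_annotations(notes, 100L)
  expect_equal(canonical_format_string(parsed$format), long)
  expect_equal(contact_count(parsed$format), 64L)
})

test_that("task inference prefers explicit declarations, then coverage", {
  mknotes <- function(...) do.call(rbind, list(...))
  p1 <- parse_annotations(mknotes(trc_note(0L, "Task;SPESclin"),
                                  trc_note(10L, "Sl_on"),
                                  trc_note(600L, "Sl_off")), 1000L)
  expect_equal(infer_task(p1), "SPESclin")
  p2 <- parse_annotations(mknotes(trc_note(10L, "Sl_on"),
                                  trc_note(600L, "Sl_off"),
                                  trc_note(650L, "Sz_on"),
                                  trc_note(700L, "Sz_off")), 1000L)
  expect_equal(infer_task(p2), "sleep")
  p3 <- parse_annotations(mknotes(trc_note(10L, "Good_on"),
                                  trc_note(600L, "Good_off")), 1000L)
  expect_equal(infer_task(p3), "rest")
})
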