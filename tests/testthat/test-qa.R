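# one small demo study shared by the validator tests in this file
demo_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      out <- file.path(tempdir(), "qa-demo-study")
      unlink(out, recursive = TRUE)
      cache <<- generate_demo_study(demo_study_spec(2, 1, 1, seed = 5), out)
    }
    cache
  }
})

test_that("generated demo studies pass structural validation", {
  res <- demo_once()
  va <- validate_dataset(res$acute_root)
  vl <- validate_dataset(res$longterm_root)
  expect_true(va$passed)
  expect_true(vl$passed)
  expect_equal(sum(va$issues$severity == "error"), 0L)
  expect_equal(sum(vl$issues$severity == "error"), 0L)
})

test_that("deleting a channels.tsv produces exactly one error citing it", {
  res <- demo_once()
  copy <- file.path(tempdir(), "qa-broken")
  unlink(copy, recursive = TRUE)
  dir.create(copy)
  file.copy(res$acute_root, copy, recursive = TRUE)
  root <- file.path(copy, basename(res$acute_root))
  victim <- list.files(root, pattern = "_channels\\.tsv$", recursive = TRUE,
                       full.names = TRUE)[1]
  unlink(victim)
  report <- validate_dataset(root)
  errs <- report$issues[report$issues$severity == "error", ]
  expect_false(report$passed)
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$code, "SIDECAR_MISSING")
  expect_match(errs$path, "_channels\\.tsv$")
})

test_that("a five-digit run label is flagged as a format error", {
  res <- demo_once()
  copy <- file.path(tempdir(), "qa-runlabel")
  unlink(copy, recursive = TRUE)
  dir.create(copy)
  file.copy(res$longterm_root, copy, recursive = TRUE)
  root <- file.path(copy, basename(res$longterm_root))
  vhdr <- list.files(root, pattern = "_run-021315_ieeg\\.vhdr$",
                     recursive = TRUE, full.names = TRUE)[1]
  expect_false(is.na(vhdr))
  for (f in list.files(dirname(vhdr), full.names = TRUE)) {
    file.rename(f, gsub("run-021315", "run-21315", f))
  }
  report <- validate_dataset(root)
  expect_true("RUN_LABEL_FORMAT" %in% report$issues$code)
})

test_that("cohort composition and determinism of the demo generator", {
  res <- demo_once()
  n_sub <- function(root) {
    sum(grepl("^sub-", basename(list.dirs(root, recursive = FALSE))))
  }
  expect_equal(n_sub(res$acute_root), 2L)
  expect_equal(n_sub(res$longterm_root), 2L)
  expect_equal(nrow(res$registry$entries), 4L)

  # acute subjects have >= 2 situations incl. a post-resection stage
  for (sd in list.dirs(res$acute_root, recursive = FALSE)) {
    if (!grepl("^sub-", basename(sd))) next
    ses <- basename(list.dirs(sd, recursive = FALSE))
    expect_gte(length(ses), 2L)
    expect_true(any(grepl("^ses-SITUATION1", ses)))
    nums <- as.integer(sub("^ses-SITUATION([0-9]+).*$", "\\1", ses))
    expect_equal(sum(nums == max(nums)), 1L)  # unique post-resection stage
  }

  # long-term subjects have runs on two monitoring days with sleep + seizure
  for (sd in list.dirs(res$longterm_root, recursive = FALSE)) {
    if (!grepl("^sub-", basename(sd))) next
    vhdrs <- list.files(sd, pattern = "_ieeg\\.vhdr$", recursive = TRUE)
    days <- unique(substr(sub(".*_run-", "", vhdrs), 1, 2))
    expect_gte(length(days), 2L)
    for (ev in list.files(sd, pattern = "_events\\.tsv$", recursive = TRUE,
                          full.names = TRUE)) {
      tt <- read.delim(ev)$trial_type
      expect_true("sleep" %in% tt)
      expect_true("seizure" %in% tt)
    }
  }
})

test_that("empty study specs yield valid empty roots", {
  out <- file.path(tempdir(), "qa-empty")
  unlink(out, recursive = TRUE)
  res <- generate_demo_study(demo_study_spec(0, 0, 0, seed = 1), out)
  expect_true(validate_dataset(res$acute_root)$passed)
  expect_true(validate_dataset(res$longterm_root)$passed)
  expect_true(file.exists(file.path(res$acute_root,
                                    "dataset_description.json")))
})

test_that("no synthetic identity leaks into either dataset tree", {
  res <- demo_once()
  leaks <- rbind(audit_identity_leaks(res$acute_root, res$denylist),
                 audit_identity_leaks(res$longterm_root, res$denylist))
  expect_equal(nrow(leaks), 0L)
  # the audit does catch a planted token
  planted <- file.path(res$acute_root, "sub-RESP0001")
  f <- list.files(planted, pattern = "_events\\.tsv$", recursive = TRUE,
                  full.names = TRUE)[1]
  tmp_root <- file.path(tempdir(), "qa-leak")
  unlink(tmp_root, recursive = TRUE); dir.create(tmp_root)
  writeLines(c(readLines(f), res$denylist[1]), file.path(tmp_root, "x.tsv"))
  expect_equal(nrow(audit_identity_leaks(tmp_root, res$denylist)), 1L)
})

test_that("validator reports zero errors across random seeds", {
  for (seed in c(2, 3)) {
    out <- file.path(tempdir(), paste0("qa-seed-", seed))
    unlink(out, recursive = TRUE)
    res <- generate_demo_study(demo_study_spec(1, 1, 0, seed = seed), out)
    expect_true(validate_dataset(res$acute_root)$passed)
    expect_true(validate_dataset(res$longterm_root)$passed)
  }
})
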