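test_that("EDF round-trip preserves signals within 16-bit quantization", {
  rec <- quick_recording(seed = 4, duration_s = 10)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(dim(back$signals), dim(rec$signals))
  rng <- apply(rec$signals, 1, function(x) diff(range(x)))
  err <- apply(abs(back$signals - rec$signals), 1, max)
  expect_true(all(err < 1e-3 * rng))
})

test_that("EDF dimensions and sampling rates survive write/read", {
  fs <- 256
  rec <- new_recording(matrix(rnorm(2 * 10 * fs), 2), fs, c("Cz", "Pz"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(dim(back$signals), c(2L, 2560L))

  rec512 <- new_recording(matrix(rnorm(2 * 10 * 512), 2), 512, c("Cz", "Pz"))
  write_edf(rec512, path)
  expect_equal(read_edf(path)$sampling_rate, 512)
})

test_that("read_edf rejects garbage and missing files", {
  expect_error(read_edf(tempfile()), class = "eegprog_format")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF file at all", bad)
  expect_error(read_edf(bad), class = "eegprog_format")
})

test_that("channel label normalization maps clinical synonyms", {
  expect_equal(normalize_channel_labels(c("EEG T3-REF", "t4", "T5", "T6", "FP1", "cz")),
               c("T7", "T8", "P7", "P8", "Fp1", "Cz"))
  expect_equal(normalize_channel_labels("A1"), "A1")  # mastoid kept verbatim
})

test_that("montages satisfy their geometric and set invariants", {
  ld <- load_montage("ld1020")
  hd <- load_montage("hd91")
  expect_length(ld$labels, 19)
  expect_length(hd$labels, 91)
  expect_true(all(c("Fp1", "Fz", "Cz", "Pz", "O2") %in% ld$labels))
  expect_true(all(ld$labels %in% hd$labels))
  expect_false(anyDuplicated(hd$labels) > 0)
  norms <- sqrt(rowSums(hd$coordinates^2))
  expect_true(all(norms > 0.99 & norms < 1.01))
  expect_error(load_montage("foo"), class = "eegprog_unknown_montage")
})

test_that("montage CSV round-trips", {
  m <- load_montage("ld1020")
  path <- withr::local_tempfile(fileext = ".csv")
  write_montage(m, path)
  back <- read_montage(path, name = "ld1020")
  expect_equal(back$labels, m$labels)
  expect_equal(unname(back$coordinates), unname(m$coordinates), tolerance = 1e-12)
})

test_that("subset_channels honors order, composes, and errors on misses", {
  rec <- quick_recording(seed = 2, duration_s = 10, montage = "hd91")
  same <- subset_channels(rec, rec$channel_labels)
  expect_equal(same$signals, rec$signals)

  ld_labels <- load_montage("ld1020")$labels
  sub <- subset_channels(rec, ld_labels)
  expect_equal(nrow(sub$signals), 19)
  expect_equal(sub$channel_labels, ld_labels)

  two_step <- subset_channels(subset_channels(rec, ld_labels), c("Cz", "Pz"))
  one_step <- subset_channels(rec, c("Cz", "Pz"))
  expect_equal(two_step$signals, one_step$signals)

  expect_error(subset_channels(rec, "Nonexistent"),
               class = "eegprog_missing_channel", regexp = "Nonexistent")
})

test_that("channel subsetting commutes with per-channel filtering", {
  rec <- quick_recording(seed = 8, duration_s = 20, montage = "hd91")
  labels <- c("Cz", "Pz", "O1")
  a <- subset_channels(bandpass_filter(rec), labels)
  b <- bandpass_filter(subset_channels(rec, labels))
  expect_equal(a$signals, b$signals, tolerance = 1e-8)
})

test_that("the bundled cohort table reads with the documented structure", {
  coh <- read_cohort(example_cohort_path())
  expect_equal(nrow(coh), 18)
  expect_equal(coh$gose_3mo[coh$id == "8"], 4)
  expect_equal(sum(is.na(coh$gose_6mo)), 1)
  expect_true(is.na(coh$gose_6mo[coh$id == "15"]))
})

test_that("cohort read -> write -> read is idempotent", {
  coh <- read_cohort(example_cohort_path())
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  again <- read_cohort(path)
  expect_equal(as.data.frame(again), as.data.frame(coh))
})

test_that("cohort validation rejects out-of-range and degenerate input", {
  coh <- read_cohort(example_cohort_path())
  bad <- coh; bad$gcs_total[3] <- 16
  expect_error(validate_cohort(bad), class = "eegprog_cohort", regexp = "gcs_total")
  bad <- coh; bad$ct_grade[1] <- 0
  expect_error(validate_cohort(bad), class = "eegprog_cohort", regexp = "ct_grade")
  bad <- coh; bad$gose_3mo[2] <- 9
  expect_error(validate_cohort(bad), class = "eegprog_cohort")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,sex,age_years,ct_grade,days_since_injury,gcs_total,gose_3mo,gose_6mo", empty)
  expect_error(read_cohort(empty), class = "eegprog_cohort")
})
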