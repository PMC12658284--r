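test_that("EDF round-trip preserves samples to 16-bit quantization and fs exactly", {
  set.seed(11)
  sig <- matrix(rnorm(256 * 60 * 8, sd = 20), ncol = 8,
                dimnames = list(NULL, montage()$labels))
  rec <- eeg_recording(sig, 256)
  expect_equal(rec$duration_s, 60)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  r2 <- read_recording(path)
  expect_equal(r2$fs, 256)
  expect_equal(r2$duration_s, 60)
  expect_identical(colnames(r2$signal), montage()$labels)
  half_step <- vapply(seq_len(8), function(k)
    signif(max(abs(sig[, k])) * 1.001, 4) / 65535, numeric(1))
  for (k in seq_len(8))
    expect_lt(max(abs(r2$signal[, k] - sig[, k])), half_step[k] * 1.01)
})

test_that("decorated channel labels normalize to canonical montage names", {
  expect_identical(
    normalize_channel_label(c("EEG Fp1-Ref", "fp2-REF", "EEG C3-Ref", "O2")),
    c("Fp1", "Fp2", "C3", "O2"))
  expect_true(is.na(normalize_channel_label("EEG Cz-Ref")))
})

test_that("python mne reads our EDF identically (independent format oracle)", {
  set.seed(12)
  sig <- matrix(rnorm(64 * 20 * 8, sd = 20), ncol = 8,
                dimnames = list(NULL, montage()$labels))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(eeg_recording(sig, 64), path)
  out_csv <- withr::local_tempfile(fileext = ".csv")
  script <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf(%s, verbose='error')\n",
    "np.savetxt(%s, raw.get_data()[:, :50].T * 1e6, delimiter=',')\n"),
    deparse(path), deparse(out_csv))
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(script, py)
  status <- system2("python", py, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  got <- as.matrix(utils::read.csv(out_csv, header = FALSE))
  ours <- read_recording(path)$signal[1:50, ]
  expect_lt(max(abs(got - ours)), 1e-6)
})

test_that("a missing montage channel is reported by name", {
  set.seed(13)
  sig <- matrix(rnorm(64 * 4 * 8), ncol = 8,
                dimnames = list(NULL, montage()$labels))
  rec <- eeg_recording(sig, 64)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  # corrupt the O2 label in place (signal header field 8 of 16 bytes)
  con <- file(path, "r+b")
  seek(con, 256 + 7 * 16, rw = "write")
  writeBin(charToRaw(formatC("EEG Oz-Ref", width = 16, flag = "-")), con)
  close(con)
  expect_error(read_recording(path), "O2 not found")
  expect_error(read_recording(withr::local_tempfile(fileext = ".edf")), "not found")
})

test_that("marker CSV round-trip is exact and pairing errors are caught", {
  mk <- marker_set(data.frame(onset_s = c(100, 400.25), termination_s = c(220.5, 470)),
                   interictal = c(1000, 2000.75))
  path <- withr::local_tempfile(fileext = ".csv")
  write_markers(mk, path)
  m2 <- read_markers(path)
  expect_equal(m2$seizures$onset_s, mk$seizures$onset_s)
  expect_equal(m2$seizures$termination_s, mk$seizures$termination_s)
  expect_equal(m2$interictal, mk$interictal)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("kind,time_s,label", "onset,100,", "onset,150,"), bad)
  expect_error(read_markers(bad), "unpaired")
  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("kind,time_s,label", "interictal,-5,"), neg)
  expect_error(read_markers(neg), "non-negative")
  direct <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("kind,time_s,label", "onset,100,", "termination,220,",
               "interictal,600,"), direct)
  m3 <- read_markers(direct)
  expect_equal(nrow(m3$seizures), 1L)
  expect_equal(m3$seizures$onset_s, 100)
  expect_equal(m3$interictal, 600)
})

test_that("seizure selection filters by duration, honors exclusions, drops near markers", {
  mk <- marker_set(data.frame(onset_s = c(0, 100, 200), termination_s = c(30, 115, 350)),
                   interictal = 310)
  sel <- suppressWarnings(select_seizures(mk, min_count = 50))
  expect_equal(sel$markers$seizures$onset_s, c(0, 200))
  expect_equal(sel$report$rejected$seizure, 2L)
  expect_match(sel$report$rejected$reason, "duration")
  expect_equal(sel$report$n_retained + nrow(sel$report$rejected), sel$report$n_input)
  # marker at 310 is 40 s from termination 350 -> dropped by the 300 s rule
  expect_length(sel$markers$interictal, 0L)
  expect_equal(sel$report$n_interictal_dropped, 1L)
  expect_warning(select_seizures(mk, min_count = 50), "< 50")

  # manual exclusion flag
  mk2 <- marker_set(data.frame(onset_s = c(0, 100), termination_s = c(50, 180),
                               exclude = c(FALSE, TRUE)))
  sel2 <- suppressWarnings(select_seizures(mk2, min_count = 1))
  expect_equal(nrow(sel2$markers$seizures), 1L)
  expect_match(sel2$report$rejected$reason, "excluded")

  # idempotence
  sel3 <- suppressWarnings(select_seizures(sel$markers, min_count = 50))
  expect_equal(sel3$markers$seizures, sel$markers$seizures)
  expect_equal(sel3$markers$interictal, sel$markers$interictal)
  expect_equal(nrow(sel3$report$rejected), 0L)
})

test_that("marker-set invariants are enforced", {
  expect_error(marker_set(data.frame(onset_s = 10, termination_s = 5)), "onset")
  expect_error(marker_set(data.frame(onset_s = c(0, 20), termination_s = c(30, 60))),
               "overlap")
  expect_error(marker_set(data.frame(onset_s = -1, termination_s = 5)),
               "non-negative")
})
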