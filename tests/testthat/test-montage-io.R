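test_that("spherical montage is deterministic, unit-norm and quasi-uniform", {
  m4 <- build_spherical_montage(4)
  expect_equal(sqrt(rowSums(m4^2)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(nrow(unique(round(m4, 10))), 4L)
  expect_identical(build_spherical_montage(64, seed = 2),
                   build_spherical_montage(64, seed = 2))
  expect_error(build_spherical_montage(2), "at least 3")

  m <- build_spherical_montage(204)
  ang <- acos(pmin(pmax(tcrossprod(m), -1), 1))
  diag(ang) <- Inf
  nn <- apply(ang, 1L, min)
  expect_gt(min(nn), 0)
  expect_lt(max(nn) / min(nn), 2.5)
})

test_that("delimited recording round-trip is an identity", {
  path <- withr::local_tempfile(fileext = ".tsv")
  mont <- fix_montage(3)
  rec <- eeg_recording(matrix(c(1.5, -2, 0.25, 3, 1e-3, -7.125,
                                2.5, 0, 1, -1, 4, 2), nrow = 3),
                       sfreq = 125, channel_names = c("C1", "C2", "C3"),
                       montage = mont, subject_id = "sub1", group = "patient")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(dim(back$data), c(3L, 4L))
  expect_equal(back$sfreq, 125)
  expect_equal(back$data, rec$data, tolerance = 1e-9)
  expect_identical(back$channel_names, rec$channel_names)
  expect_equal(back$montage, rec$montage, tolerance = 1e-9)
  expect_identical(back$group, "patient")
})

test_that("EDF round-trip reproduces data within 16-bit quantization", {
  f <- fix_recording(n_ch = 16, duration_s = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(f$rec, path)
  back <- read_recording(path)
  expect_identical(back$channel_names, f$rec$channel_names)
  expect_equal(back$sfreq, f$rec$sfreq)
  expect_equal(ncol(back$data), ncol(f$rec$data))
  # physical range is +/- 8x channel max, so the step is max/4096 per channel
  step <- 16 * apply(abs(f$rec$data), 1, max) / 65534
  expect_true(all(abs(back$data - f$rec$data) <= 1.01 * step + 1e-12))
  expect_identical(back$subject_id, f$rec$subject_id)
})

test_that("a five-minute-sized recording survives a write/read cycle", {
  mont <- fix_montage(24)
  rec <- eeg_recording(matrix(sin(seq_len(24 * 37500) / 50), nrow = 24),
                       sfreq = 125, montage = mont, reference = "average")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("reader rejects malformed input with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# channels=a,b,c", "1\t2", "3\t4", "5\t6"), path)
  expect_error(read_recording(path), "sfreq")
  writeLines(c("# sfreq=125", "# channels=a,b,c",
               "1\t2", "3\tx", "5\t6"), path)
  expect_error(read_recording(path), "row 2, column 2")
  writeLines(c("# sfreq=125", "# channels=a,b", "1\t2", "3\t4", "5\t6"), path)
  expect_error(read_recording(path), "channel names")
  expect_error(eeg_recording(matrix(c(1, 2, NaN, 4, 5, 6), nrow = 3),
                             125, c("c1", "c2", "c3")),
               "channel c3, sample 1")
})

test_that("template, label and parameter tables round-trip exactly", {
  tpl <- fix_templates(16, 4)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_templates(tpl, tf)
  tpl2 <- read_templates(tf)
  expect_equal(tpl2$maps, tpl$maps, tolerance = 1e-9)
  expect_identical(tpl2$class_labels, tpl$class_labels)
  expect_identical(tpl2$level, tpl$level)

  ser <- label_series(rep(c(1L, 2L, 1L, 3L), times = c(5, 3, 8, 4)),
                      runif(20), 125, c("A", "B", "C"))
  lf <- withr::local_tempfile(fileext = ".tsv")
  write_labels(ser, lf)
  ser2 <- read_labels(lf)
  expect_identical(ser2$labels, ser$labels)
  expect_identical(rle(ser2$labels)$lengths, rle(ser$labels)$lengths)
  expect_equal(ser2$corr, ser$corr, tolerance = 1e-9)

  params <- data.frame(subject_id = "S001", group = "control",
                       class = c("A", "B"), gev = c(0.4, 0.3),
                       mean_duration_ms = c(88, 92),
                       time_coverage_pct = c(60, 40),
                       occurrence_per_min = c(409.09, 260.87))
  pf <- withr::local_tempfile(fileext = ".tsv")
  write_parameters(params, pf)
  expect_equal(read_parameters(pf), params, tolerance = 1e-9)
})

test_that("covariate table validation enforces keys", {
  cf <- withr::local_tempfile(fileext = ".csv")
  write_covariates(data.frame(subject_id = c("a", "b"),
                              group = c("patient", "control"),
                              SDMT = c(55, 60)), cf)
  cov <- read_covariates(cf)
  expect_identical(cov$subject_id, c("a", "b"))
  write.csv(data.frame(subject_id = c("a", "a"), group = "x"), cf,
            row.names = FALSE)
  expect_error(read_covariates(cf), "duplicate")
})
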