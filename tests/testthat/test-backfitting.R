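test_that("labelling exact template samples reproduces the generative sequence", {
  f <- fix_exact_recording(n_ch = 16, K = 3, n = 300)
  ser <- assign_labels(f$rec, f$templates)
  expect_identical(ser$labels, f$states)
  expect_true(all(ser$corr > 1 - 1e-9))

  flip <- f$rec
  sgn <- sample(c(-1, 1), 300, replace = TRUE)
  flip$data <- flip$data * rep(sgn, each = 16)
  expect_identical(assign_labels(flip, f$templates)$labels, f$states)
})

test_that("noisy semi-Markov recordings are labelled almost perfectly away from boundaries", {
  f <- fix_recording(64, 4, duration_s = 30, snr = 1e9, seed = 41)
  ser <- assign_labels(f$rec, f$templates)
  expect_gt(mean(ser$labels == f$states), 0.999)
})

test_that("zero-variance samples inherit the previous label", {
  f <- fix_exact_recording(n_ch = 8, K = 2, n = 40)
  rec <- f$rec
  rec$data[, 25] <- 0
  ser <- assign_labels(rec, f$templates)
  expect_identical(ser$labels[25], ser$labels[24])
  expect_equal(ser$corr[25], 0)
  expect_equal(attr(ser, "n_zero_variance"), 1L)
})

test_that("run-length smoothing absorbs short runs and is idempotent", {
  ser <- label_series(rep(c(1L, 2L, 1L), times = c(10, 1, 10)),
                      rep(0.9, 21), 125, c("A", "B"))
  expect_identical(smooth_labels(ser, 0)$labels, ser$labels)
  sm <- smooth_labels(ser, 24)
  expect_true(all(sm$labels == 1L))
  expect_identical(smooth_labels(sm, 24)$labels, sm$labels)

  set.seed(7)
  rnd <- label_series(sample(1:3, 400, replace = TRUE), runif(400), 125,
                      c("A", "B", "C"))
  out <- smooth_labels(rnd, 24)
  runs <- rle(out$labels)
  interior <- runs$lengths[-c(1, length(runs$lengths))]
  expect_true(all(interior >= 3))
})

test_that("temporal parameters match hand arithmetic", {
  ser <- label_series(rep(c(1L, 2L), each = 5), rep(1, 10), 125, c("A", "B"))
  p <- compute_parameters(ser)
  expect_equal(p$time_coverage_pct, c(50, 50))
  expect_equal(p$mean_duration_ms, c(40, 40))
  expect_equal(p$occurrence_per_min, c(750, 750))

  single <- label_series(rep(1L, 250), rep(1, 250), 125, "A")
  ps <- compute_parameters(single)
  expect_equal(ps$time_coverage_pct, 100)
  expect_equal(ps$mean_duration_ms, 2000)
  expect_equal(ps$occurrence_per_min, 30)
})

test_that("a template-built recording is fully explained (GEV sums to 1)", {
  f <- fix_exact_recording(n_ch = 16, K = 3, n = 300)
  ser <- assign_labels(f$rec, f$templates)
  gfp <- compute_gfp(f$rec)
  p <- compute_parameters(ser, gfp, f$rec, f$templates)
  expect_equal(sum(p$gev), 1, tolerance = 1e-9)
})

test_that("coverage conservation and the TC = occ x MD / 600 identity hold", {
  f <- fix_recording(32, 4, duration_s = 20, seed = 43)
  tpl <- f$templates
  ser <- assign_labels(f$rec, tpl)
  p <- compute_parameters(ser, compute_gfp(f$rec), f$rec, tpl)
  expect_equal(sum(p$time_coverage_pct), 100, tolerance = 1e-9)
  expect_equal(p$time_coverage_pct,
               p$occurrence_per_min * p$mean_duration_ms / 600,
               tolerance = 1e-6)
})

test_that("parameters are invariant to polarity flips and channel permutation", {
  f <- fix_recording(16, 3, duration_s = 20, seed = 47)
  tpl <- f$templates
  base <- compute_parameters(assign_labels(f$rec, tpl),
                             compute_gfp(f$rec), f$rec, tpl)

  flip <- f$rec
  sgn <- sample(c(-1, 1), ncol(flip$data), replace = TRUE)
  flip$data <- flip$data * rep(sgn, each = 16)
  p_flip <- compute_parameters(assign_labels(flip, tpl),
                               compute_gfp(flip), flip, tpl)
  expect_equal(p_flip[, -1], base[, -1], tolerance = 1e-9)

  perm <- sample(16)
  rec_p <- eeg_recording(f$rec$data[perm, ], f$rec$sfreq,
                         channel_names = f$rec$channel_names[perm],
                         montage = f$rec$montage[perm, ],
                         reference = "average")
  tpl_p <- template_set(tpl$maps[, perm], class_labels = tpl$class_labels,
                        channel_names = tpl$channel_names[perm])
  p_perm <- compute_parameters(assign_labels(rec_p, tpl_p),
                               compute_gfp(rec_p), rec_p, tpl_p)
  expect_equal(p_perm[, -1], base[, -1], tolerance = 1e-9)
})

test_that("cohort back-fitting is deterministic and validates channels", {
  f <- fix_recording(16, 3, duration_s = 10, seed = 53)
  recs <- list(f$rec, f$rec, f$rec)
  for (i in seq_along(recs)) recs[[i]]$subject_id <- sprintf("S%03d", i)
  tab <- backfit_cohort(recs, f$templates)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$time_coverage_pct[1:3], tab$time_coverage_pct[4:6])
  expect_equal(tab$gev[1:3], tab$gev[7:9])

  bad <- recs
  bad[[2]]$channel_names <- rev(bad[[2]]$channel_names)
  dimnames(bad[[2]]$data)[[1]] <- bad[[2]]$channel_names
  expect_error(backfit_cohort(bad, f$templates), "S002")
})

test_that("predict() back-fits through the S3 interface", {
  f <- fix_recording(16, 3, duration_s = 20, seed = 59)
  fit <- microstates(f$rec, k = 3, n_restarts = 5, seed = 59)
  ser <- predict(fit)
  expect_s3_class(ser, "label_series")
  expect_length(ser$labels, ncol(f$rec$data))
  ser_sm <- predict(fit, min_duration_ms = 24)
  runs <- rle(ser_sm$labels)
  expect_true(all(runs$lengths[-c(1, length(runs$lengths))] >= 3))
})
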