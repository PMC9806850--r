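test_that("GFP equals the spatial standard deviation and is homogeneous", {
  rec <- eeg_recording(matrix(c(2, -1, -1, 5, 5, 5), 3), 125,
                       reference = "average")
  g <- suppressWarnings(compute_gfp(rec))
  expect_equal(g$values[1], sqrt(2), tolerance = 1e-12)
  expect_equal(g$values[2], 0, tolerance = 1e-12)

  f <- fix_exact_recording(n_ch = 8, K = 2, n = 50)
  g1 <- compute_gfp(f$rec)$values
  rec3 <- f$rec; rec3$data <- -3 * rec3$data
  expect_equal(compute_gfp(rec3)$values, 3 * g1, tolerance = 1e-12)
})

test_that("GFP peak detection finds strict maxima with separation and tie rules", {
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0), 125, min_separation_ms = 8),
                   c(2L, 4L))
  # 10 ms separation at 125 Hz needs >= 1.25 samples: adjacent peaks thinned
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0), 125, min_separation_ms = 20),
                   4L)
  expect_length(find_gfp_peaks(1:10, 125), 0)
  expect_identical(find_gfp_peaks(c(0, 1, 1, 0), 125), 2L)
  expect_length(find_gfp_peaks(c(5, 1, 0), 125), 0)  # endpoints never peaks
})

test_that("spatial correlation is scale-, polarity- and centring-aware", {
  u <- c(1, -2, 4, -3)
  expect_equal(spatial_correlation(u, 2 * u), 1, tolerance = 1e-12)
  expect_equal(spatial_correlation(u, -u), 1, tolerance = 1e-12)
  expect_equal(spatial_correlation(u, -u, polarity_invariant = FALSE), -1,
               tolerance = 1e-12)
  expect_equal(spatial_correlation(c(1, -1, 0), c(1, 1, -2)), 0,
               tolerance = 1e-12)
  expect_error(spatial_correlation(c(1, 1, 1), u[1:3]), "zero-variance")
})

test_that("modified k-means recovers noiseless structure exactly", {
  # sign-flipped copies of 2 orthogonal templates
  t1 <- c(1, -1, 1, -1, 0, 0) - 0; t1 <- t1 - mean(t1); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(1, 1, -1, -1, 1, -1); t2 <- t2 - mean(t2); t2 <- t2 / sqrt(sum(t2^2))
  maps <- rbind(t1, -t1, 2 * t1, t2, -3 * t2, t2)
  fit <- modified_kmeans(maps, 2, n_restarts = 10, seed = 1)
  expect_equal(fit$gev_total, 1, tolerance = 1e-9)
  r <- abs(fit$templates$maps %*% cbind(t1, t2))
  expect_equal(unname(sort(apply(r, 1L, max))), c(1, 1), tolerance = 1e-9)
  expect_equal(sum(fit$gev_per_class), fit$gev_total, tolerance = 1e-9)

  # K = M: every map its own template
  noisy <- maps + matrix(rnorm(36, sd = 0.1), 6)
  expect_equal(modified_kmeans(noisy, 6, n_restarts = 5, seed = 1)$gev_total, 1,
               tolerance = 1e-9)
})

test_that("best-restart GEV equals the exhaustive two-partition optimum", {
  set.seed(42)
  tpl <- fix_templates(12, 2, seed = 11)
  idx <- rep(1:2, 6)
  maps <- tpl$maps[idx, ] * runif(12, 0.5, 2) * sample(c(-1, 1), 12, TRUE) +
    matrix(rnorm(12 * 12, sd = 0.12), 12, 12)
  fit <- modified_kmeans(maps, 2, n_restarts = 50, seed = 5)
  expect_equal(fit$gev_total, oracle_best_gev_k2(maps), tolerance = 1e-9)
})

test_that("GEV is monotone across iterations and across K", {
  f <- fix_recording(16, 3, duration_s = 20, seed = 13)
  fit <- microstates(f$rec, k = 3, n_restarts = 5, seed = 13)
  expect_true(all(diff(fit$gev_trace) > -1e-12))

  peak_maps <- t(f$rec$data[, fit$peak_indices])
  gevs <- vapply(2:5, function(K)
    modified_kmeans(peak_maps, K, n_restarts = 20, seed = 2)$gev_total,
    numeric(1))
  expect_true(all(diff(gevs) > -1e-9))
})

test_that("clustering is invariant to polarity flips and equivariant to channel permutation", {
  f <- fix_recording(16, 3, duration_s = 15, seed = 17)
  fit <- microstates(f$rec, k = 3, n_restarts = 5, seed = 17)
  peak_maps <- t(f$rec$data[, fit$peak_indices])

  flips <- sample(c(-1, 1), nrow(peak_maps), replace = TRUE)
  fit_flip <- modified_kmeans(peak_maps * flips, 3, n_restarts = 5, seed = 17)
  fit_base <- modified_kmeans(peak_maps, 3, n_restarts = 5, seed = 17)
  expect_equal(fit_flip$gev_total, fit_base$gev_total, tolerance = 1e-9)

  perm <- sample(ncol(peak_maps))
  fit_perm <- modified_kmeans(peak_maps[, perm], 3, n_restarts = 5, seed = 17)
  expect_equal(fit_perm$gev_total, fit_base$gev_total, tolerance = 1e-9)
  m <- match_templates(fit_perm$templates$maps, fit_base$templates$maps[, perm])
  expect_true(all(m$abs_correlation > 1 - 1e-9))
})

test_that("segmentation front end is deterministic and rejects degenerate input", {
  f <- fix_recording(16, 3, duration_s = 15, seed = 19)
  f1 <- microstates(f$rec, k = 3, n_restarts = 5, seed = 19)
  f2 <- microstates(f$rec, k = 3, n_restarts = 5, seed = 19)
  expect_identical(f1$templates$maps, f2$templates$maps)
  expect_identical(f1$assignment, f2$assignment)

  const <- eeg_recording(matrix(1, 8, 500), 125, reference = "average")
  expect_error(suppressWarnings(microstates(const, k = 2)), "too few")
})

test_that("meta-criterion handles degenerate ranges and flags structureless maps", {
  f <- fix_recording(16, 4, duration_s = 20, seed = 23)
  peak_maps <- t(f$rec$data[, compute_gfp(f$rec)$peak_indices])
  expect_identical(meta_criterion(peak_maps, K_range = 3,
                                  n_restarts = 5)$meta_optimal_K, 3L)

  set.seed(1)
  noise_maps <- matrix(rnorm(120 * 16), 120, 16)
  expect_warning(rep_noise <- meta_criterion(noise_maps, K_range = 2:6,
                                             n_restarts = 5, seed = 1),
                 "non-concordant")
  expect_true(rep_noise$meta_optimal_K %in% 2:6)
})

test_that("group segmentation pools subjects order-invariantly", {
  sets <- lapply(1:4, function(i) fix_templates(16, 3, seed = i))
  same <- group_segmentation(rep(sets[1], 3), k = 3, n_restarts = 10, seed = 1)
  m <- match_templates(same$templates, sets[[1]])
  expect_true(all(m$abs_correlation > 1 - 1e-9))
  expect_identical(same$templates$level, "group")

  g1 <- group_segmentation(sets, k = 3, n_restarts = 20, seed = 2)
  g2 <- group_segmentation(rev(sets), k = 3, n_restarts = 20, seed = 2)
  expect_equal(g1$gev_total, g2$gev_total, tolerance = 1e-6)
})

test_that("template matching recovers permutations and beats brute force", {
  tpl <- fix_templates(16, 4, seed = 31)
  m_id <- match_templates(tpl, tpl)
  expect_identical(m_id$index1, m_id$index2)
  expect_true(all(m_id$abs_correlation > 1 - 1e-12))

  perm <- c(3L, 1L, 4L, 2L)
  tpl_p <- template_set(tpl$maps[perm, ], channel_names = tpl$channel_names)
  m <- match_templates(tpl, tpl_p)
  expect_identical(order(m$index2), perm[order(perm[m$index2])])
  expect_identical(m$index2[perm], seq_len(4L))

  # 2x2 brute force: both assignments enumerated by hand
  a <- fix_templates(8, 2, seed = 33)
  b <- fix_templates(8, 2, seed = 34)
  R <- abs(tcrossprod(a$maps, b$maps))
  best_hand <- max(R[1, 1] + R[2, 2], R[1, 2] + R[2, 1])
  m22 <- match_templates(a, b)
  expect_equal(sum(m22$abs_correlation), best_hand, tolerance = 1e-12)
})

test_that("canonical archetype labelling assigns each class once", {
  mont <- fix_montage(64)
  arch <- canonical_archetypes(mont)
  lab <- label_microstates(arch, mont)
  expect_identical(lab$class_labels, c("A", "B", "C", "D", "E", "F"))
})
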