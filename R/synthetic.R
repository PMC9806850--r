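# Synthetic resting-state cohort with known microstate ground truth.
#
# Recordings are built as a semi-Markov sequence of quasi-stable template
# topographies (gamma-distributed dwell times, ~80-120 ms) amplitude-modulated
# by a rectified ~10 Hz carrier, plus spatially correlated Gaussian sensor
# noise. Two groups differ in their template repertoire (controls carry an
# occipital-central class F, patients a left-right class E) and in per-class
# dwell modifiers; cognitive and clinical covariates are coupled linearly to
# the *generative* microstate parameters so estimator bias is measurable.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions every recovery test runs under:
#' 64 channels, 125 Hz, 120 s per subject, mean dwell 100 ms with gamma shape
#' 4, sensor SNR 2, rectified 10 Hz GFP carrier, spatially correlated noise
#' with 0.6 rad correlation length, per-dwell polarity flips. Group effects
#' multiply the dwell means of selected classes (patients: A x1.3, B x1.2;
#' controls: D x1.3); patients draw from classes {A,B,C,D,E}, controls from
#' {A,B,C,D,F}.
#'
#' @param n_channels electrode count.
#' @param sfreq generation sampling rate (Hz).
#' @param duration_s recording length per subject (s).
#' @param mean_dwell_ms mean microstate dwell time (ms), scalar or per class.
#' @param dwell_shape gamma shape of the dwell distribution.
#' @param transition_matrix K x K matrix, zero diagonal, rows summing to 1;
#'   `NULL` = uniform off-diagonal.
#' @param gfp_carrier_hz frequency of the rectified GFP amplitude carrier.
#' @param snr template power / noise power at the sensors.
#' @param noise_spatial_scale angular correlation length of the noise (rad).
#' @param polarity_flips multiply each dwell period's template by a random sign.
#' @param control_classes,patient_classes class repertoires of the two groups.
#' @param group_effects named list of per-class dwell multipliers per group.
#' @param covariate_model coefficients coupling covariates to generative
#'   parameters: SDMT to class-A occupancy (`sdmt_beta0`, `sdmt_beta1`,
#'   `sdmt_r2` fixing the noise variance), disease duration to class-A mean
#'   dwell (`dd_mean`, `dd_sd`, `dd_r2`).
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 64, sfreq = 125, duration_s = 120,
                             mean_dwell_ms = 100, dwell_shape = 4,
                             transition_matrix = NULL, gfp_carrier_hz = 10,
                             snr = 2.0, noise_spatial_scale = 0.6,
                             polarity_flips = TRUE,
                             control_classes = c("A", "B", "C", "D", "F"),
                             patient_classes = c("A", "B", "C", "D", "E"),
                             group_effects = list(
                               patient = c(A = 1.3, B = 1.2),
                               control = c(D = 1.3)),
                             covariate_model = list(
                               sdmt_beta0 = 57, sdmt_beta1 = 150, sdmt_r2 = 0.3,
                               dd_mean = 6, dd_sd = 4, dd_r2 = 0.1),
                             seed = 1L) {
  if (snr <= 0) ms_stop("snr must be positive")
  if (any(mean_dwell_ms <= 0)) ms_stop("dwell means must be positive")
  if (!is.null(transition_matrix) &&
      (any(abs(diag(as.matrix(transition_matrix))) > 1e-12) ||
       any(abs(rowSums(as.matrix(transition_matrix)) - 1) > 1e-9)))
    ms_stop("transition matrix needs zero diagonal and unit row sums")
  structure(as.list(environment()), class = "synthetic_config")
}

harmonic_basis <- function(montage, order = 3) {
  x <- montage[, 1]; y <- montage[, 2]; z <- montage[, 3]
  b <- cbind(x, y, z)
  if (order >= 2) b <- cbind(b, x * y, x * z, y * z, x^2 - y^2, 3 * z^2 - 1)
  if (order >= 3) b <- cbind(b, z * (5 * z^2 - 3), x * (5 * z^2 - 1),
                             y * (5 * z^2 - 1), z * (x^2 - y^2), x * y * z,
                             x * (x^2 - 3 * y^2), y * (3 * x^2 - y^2))
  b
}

#' Generate K random smooth template topographies
#'
#' Each map is a random combination of low-order spherical-harmonic basis
#' functions evaluated at the electrode sites, centred and unit-normalised.
#' Maps are redrawn until all pairwise absolute spatial correlations are at
#' most 0.7 (bounded retries), so the set is identifiable by clustering.
#'
#' @param montage electrode coordinate matrix from [build_spherical_montage()].
#' @param K number of templates (<= 8).
#' @param smoothness_order maximum harmonic degree (1-3).
#' @param seed integer seed.
#' @param max_corr pairwise decorrelation bound.
#' @return a [template_set] (level `"population"`).
#' @export
make_templates <- function(montage, K, smoothness_order = 3, seed = 1L,
                           max_corr = 0.7) {
  if (K > 8) ms_stop("at most 8 templates are supported")
  validate_montage(montage)
  basis <- harmonic_basis(montage, smoothness_order)
  with_seed(derive_seed(seed, "templates"), {
    draw_map <- function() {
      w <- stats::rnorm(ncol(basis)) / seq_len(ncol(basis))^0.5
      m <- drop(basis %*% w)
      m <- m - mean(m)
      m / sqrt(sum(m^2))
    }
    maps <- matrix(0, K, nrow(montage))
    maps[1, ] <- draw_map()
    for (k in seq_len(K)[-1]) {
      ok <- FALSE
      for (try in seq_len(500)) {
        cand <- draw_map()
        if (all(abs(maps[seq_len(k - 1), , drop = FALSE] %*% cand) <= max_corr)) {
          maps[k, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) ms_stop("could not draw decorrelated templates from this seed",
                       class = "microstatr_seed_error")
    }
    template_set(maps, class_labels = LETTERS[seq_len(K)], level = "population",
                 channel_names = rownames(montage))
  })
}

#' Simulate a semi-Markov microstate state sequence
#'
#' Classes are drawn from the transition matrix; each visit's dwell time is
#' gamma-distributed (`shape = dwell_shape`, mean = the class's dwell mean),
#' rounded to at least one sample.
#'
#' @param K number of classes.
#' @param n_samples sequence length.
#' @param sfreq sampling rate (Hz).
#' @param mean_dwell_ms scalar or length-K vector of dwell means (ms).
#' @param dwell_shape gamma shape parameter.
#' @param transition_matrix K x K, zero diagonal, rows sum to 1; `NULL` =
#'   uniform off-diagonal.
#' @param seed integer seed.
#' @return list: `states` (integer vector of length `n_samples`), and
#'   `realized` — per-class occupancy, mean dwell (ms) and occurrence (/min)
#'   computed from the generated sequence.
#' @export
simulate_state_sequence <- function(K, n_samples, sfreq, mean_dwell_ms = 100,
                                    dwell_shape = 4, transition_matrix = NULL,
                                    seed = 1L) {
  if (n_samples < 1L) ms_stop("n_samples must be at least 1")
  mean_dwell_ms <- rep_len(mean_dwell_ms, K)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / max(K - 1, 1), K, K)
    diag(transition_matrix) <- 0
    if (K == 1L) transition_matrix <- matrix(0, 1, 1)
  }
  with_seed(derive_seed(seed, "state-seq"), {
    states <- integer(n_samples)
    pos <- 0L
    cur <- sample.int(K, 1L)
    while (pos < n_samples) {
      mean_samp <- mean_dwell_ms[cur] * sfreq / 1000
      dwell <- if (dwell_shape <= 0) round(mean_samp)
               else stats::rgamma(1L, shape = dwell_shape,
                                  scale = mean_samp / dwell_shape)
      dwell <- max(1L, as.integer(round(dwell)))
      take <- min(dwell, n_samples - pos)
      states[(pos + 1L):(pos + take)] <- cur
      pos <- pos + take
      cur <- if (K == 1L) 1L else
        sample.int(K, 1L, prob = transition_matrix[cur, ])
    }
    runs <- label_runs(states)
    occ <- tabulate(states, K) / n_samples
    md <- vapply(seq_len(K), function(k) {
      ln <- runs$length[runs$class == k]
      if (length(ln) == 0L) 0 else mean(ln) * 1000 / sfreq
    }, numeric(1))
    occur <- vapply(seq_len(K), function(k) sum(runs$class == k), numeric(1)) /
      (n_samples / sfreq / 60)
    list(states = states,
         realized = data.frame(class = seq_len(K), occupancy = occ,
                               mean_dwell_ms = md, occurrence_per_min = occur))
  })
}

# Smoothed rectified-sinusoid GFP envelope; local maxima arrive at roughly
# twice the carrier frequency, emulating the natural GFP peak rate.
gfp_envelope <- function(n_samples, sfreq, carrier_hz, seed) {
  with_seed(derive_seed(seed, "envelope"), {
    phase <- stats::runif(1, 0, 2 * pi)
    t <- seq_len(n_samples) / sfreq
    a <- abs(sin(2 * pi * carrier_hz * t + phase))
    L <- max(3L, round(0.040 * sfreq))          # 40 ms Hann smoothing
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
    a <- stats::filter(c(rep(a[1], L), a, rep(a[n_samples], L)), w / sum(w),
                       sides = 2)
    as.numeric(a[(L + 1):(L + n_samples)])
  })
}

correlated_noise <- function(montage, n_samples, spatial_scale, seed) {
  ang <- montage_angles(montage)
  C <- exp(-ang^2 / (2 * spatial_scale^2))
  R <- chol(C + diag(1e-8, nrow(C)))
  with_seed(derive_seed(seed, "noise"), {
    crossprod(R, matrix(stats::rnorm(nrow(montage) * n_samples),
                        nrow = nrow(montage)))
  })
}

#' Synthesise an EEG recording from templates and a state sequence
#'
#' `data(t) = s(t) a(t) T_L(t) + noise(t)`: the active template scaled by a
#' smoothed rectified-sinusoid envelope `a(t)` (and a per-dwell random sign
#' `s(t)` when polarity flips are on), plus spatially correlated Gaussian
#' noise scaled so the signal/noise power ratio equals `config$snr`. The
#' result is re-referenced to the common average.
#'
#' @param templates a [template_set] whose rows are indexed by `states`.
#' @param states integer state sequence (from [simulate_state_sequence()]).
#' @param montage electrode coordinates.
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param subject_id,group metadata for the returned recording.
#' @param return_parts also return the pure signal and noise matrices.
#' @return an [eeg_recording] (or a list with `recording`, `signal`, `noise`
#'   when `return_parts = TRUE`).
#' @export
synthesize_recording <- function(templates, states, montage, config,
                                 seed = 1L, subject_id = NA_character_,
                                 group = NA_character_, return_parts = FALSE) {
  stopifnot(inherits(templates, "template_set"))
  if (ncol(templates$maps) != nrow(montage))
    ms_stop("template channel count does not match the montage",
            class = "microstatr_structure_error")
  if (config$snr <= 0) ms_stop("snr must be positive")
  n <- length(states)
  a <- gfp_envelope(n, config$sfreq, config$gfp_carrier_hz, seed)
  sgn <- rep(1, n)
  if (isTRUE(config$polarity_flips)) {
    runs <- label_runs(states)
    sgn <- with_seed(derive_seed(seed, "polarity"), {
      rep(sample(c(-1, 1), nrow(runs), replace = TRUE), runs$length)
    })
  }
  signal <- t(templates$maps[states, , drop = FALSE]) *
    rep(a * sgn, each = nrow(montage))
  noise <- correlated_noise(montage, n, config$noise_spatial_scale, seed)
  p_sig <- mean(signal^2)
  p_noise <- mean(noise^2)
  noise <- noise * sqrt(p_sig / (config$snr * p_noise))
  # scale to a physiological RMS GFP of ~5 uV for the signal part
  scale_uv <- 5 / sqrt(mean(signal^2))
  rec <- eeg_recording((signal + noise) * scale_uv, sfreq = config$sfreq,
                       channel_names = rownames(montage), montage = montage,
                       subject_id = subject_id, group = group)
  rec <- rereference_average(rec)
  if (return_parts)
    list(recording = rec, signal = signal * scale_uv, noise = noise * scale_uv)
  else rec
}

#' Simulate a two-group synthetic cohort with ground truth
#'
#' Generates patient and control recordings sharing four canonical template
#' classes (A-D) while patients additionally carry class E and controls class
#' F; group-specific dwell modifiers are applied per `config$group_effects`.
#' Covariates are coupled to the generative (not estimated) microstate
#' parameters: SDMT linearly to class-A occupancy, disease duration to
#' class-A mean dwell, with noise variances fixed by the configured R^2.
#'
#' @param config a [synthetic_config()].
#' @param n_patients,n_controls group sizes (>= 2).
#' @param seed integer seed.
#' @return list of class `synthetic_cohort`: `recordings` (list of
#'   [eeg_recording]), `covariates` (data frame), and `ground_truth`
#'   (templates, per-subject state sequences in the 6-class label space,
#'   realized per-subject parameters, covariate coefficients, seed).
#' @export
simulate_cohort <- function(config = synthetic_config(), n_patients = 10,
                            n_controls = 10, seed = config$seed) {
  if (n_patients < 2 || n_controls < 2) ms_stop("group sizes must be >= 2")
  montage <- build_spherical_montage(config$n_channels)
  all_classes <- sort(unique(c(config$control_classes, config$patient_classes)))
  templates <- make_templates(montage, length(all_classes),
                              seed = derive_seed(seed, "cohort-templates"))
  templates$class_labels <- all_classes
  rownames(templates$maps) <- all_classes

  n_samples <- round(config$duration_s * config$sfreq)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_patients + n_controls)),
    group = rep(c("patient", "control"), c(n_patients, n_controls)),
    stringsAsFactors = FALSE)

  recordings <- vector("list", nrow(subjects))
  states_all <- vector("list", nrow(subjects))
  realized_all <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    grp <- subjects$group[i]
    classes <- if (grp == "patient") config$patient_classes else config$control_classes
    class_idx <- match(classes, all_classes)
    dwell <- rep_len(config$mean_dwell_ms, length(classes))
    names(dwell) <- classes
    eff <- config$group_effects[[grp]]
    if (!is.null(eff)) {
      hit <- intersect(names(eff), classes)
      dwell[hit] <- dwell[hit] * eff[hit]
    }
    sseed <- derive_seed(seed, paste0("subject", i))
    seq_i <- simulate_state_sequence(length(classes), n_samples, config$sfreq,
                                     mean_dwell_ms = dwell,
                                     dwell_shape = config$dwell_shape,
                                     transition_matrix = config$transition_matrix,
                                     seed = sseed)
    states_global <- class_idx[seq_i$states]
    sub_templates <- template_set(templates$maps[class_idx, , drop = FALSE],
                                  class_labels = classes, level = "population",
                                  channel_names = templates$channel_names)
    recordings[[i]] <- synthesize_recording(
      sub_templates, seq_i$states, montage, config, seed = sseed,
      subject_id = subjects$subject_id[i], group = grp)
    states_all[[i]] <- states_global
    realized <- data.frame(subject_id = subjects$subject_id[i], group = grp,
                           class = all_classes,
                           occupancy = tabulate(states_global, length(all_classes)) / n_samples,
                           mean_dwell_ms = 0, occurrence_per_min = 0,
                           stringsAsFactors = FALSE)
    runs <- label_runs(states_global)
    for (k in seq_along(all_classes)) {
      ln <- runs$length[runs$class == k]
      realized$mean_dwell_ms[k] <- if (length(ln)) mean(ln) * 1000 / config$sfreq else 0
      realized$occurrence_per_min[k] <- length(ln) / (n_samples / config$sfreq / 60)
    }
    realized_all[[i]] <- realized
  }
  realized <- do.call(rbind, realized_all)

  cm <- config$covariate_model
  occ_A <- realized$occupancy[realized$class == "A"]
  md_A <- realized$mean_dwell_ms[realized$class == "A"]
  covariates <- with_seed(derive_seed(seed, "covariates"), {
    sd_sig <- stats::sd(occ_A) * abs(cm$sdmt_beta1)
    eps_sd <- if (cm$sdmt_r2 > 0 && cm$sdmt_r2 < 1)
      sd_sig * sqrt((1 - cm$sdmt_r2) / cm$sdmt_r2) else 0
    sdmt <- cm$sdmt_beta0 + cm$sdmt_beta1 * (occ_A - mean(occ_A)) +
      stats::rnorm(length(occ_A), sd = eps_sd)
    dd_sig <- (md_A - mean(md_A)) / max(stats::sd(md_A), 1e-12) *
      cm$dd_sd * sqrt(cm$dd_r2)
    dd <- pmax(0, cm$dd_mean + dd_sig +
                 stats::rnorm(length(md_A), sd = cm$dd_sd * sqrt(1 - cm$dd_r2)))
    dd[subjects$group != "patient"] <- NA
    data.frame(subject_id = subjects$subject_id, group = subjects$group,
               age = round(stats::rnorm(nrow(subjects), 42, 11)),
               disease_duration = dd,
               EDSS = ifelse(subjects$group == "patient",
                             round(pmax(0, stats::rnorm(nrow(subjects), 1.4, 1)) * 2) / 2,
                             NA),
               ARR = ifelse(subjects$group == "patient",
                            round(stats::rgamma(nrow(subjects), 2, 4), 2), NA),
               SDMT = sdmt,
               CVLT2 = stats::rnorm(nrow(subjects), 58, 12),
               BVMTR = stats::rnorm(nrow(subjects), 54, 9),
               stringsAsFactors = FALSE)
  })

  ground_truth <- list(templates = templates, state_sequences = states_all,
                       realized = realized,
                       covariate_coefficients = cm, seed = seed,
                       class_labels = all_classes)
  structure(list(recordings = recordings, covariates = covariates,
                 ground_truth = ground_truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d recordings (%d patients / %d controls), %d channels, %.0f s at %g Hz\n",
              length(x$recordings), sum(x$covariates$group == "patient"),
              sum(x$covariates$group == "control"), x$config$n_channels,
              x$config$duration_s, x$config$sfreq))
  invisible(x)
}
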