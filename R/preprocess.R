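# Preprocessing chain: band-pass filter -> resample -> spherical-spline
# interpolation of bad channels -> common average reference. The runner
# enforces this order. Filtering and resampling are delegated to the `signal`
# package; the spherical spline (Perrin-style) is implemented here.

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth applied forward and backward (`filtfilt`), giving
#' a zero-phase response so scalp topographies are not distorted by
#' channel-wise phase shifts. Edges are padded by reflection.
#'
#' @param rec an [eeg_recording].
#' @param low,high band edges in Hz (defaults 1 and 40).
#' @param order Butterworth order per pass.
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, low = 1, high = 40, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  if (!(0 < low && low < high && high < nyq))
    ms_stop(sprintf("band [%g, %g] Hz invalid for Nyquist %g Hz", low, high, nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  n <- ncol(rec$data)
  pad <- min(n - 1L, ceiling(3 * rec$sfreq / low))
  out <- t(apply(rec$data, 1L, function(x) {
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  }))
  rec$data <- out
  dimnames(rec$data) <- list(rec$channel_names, NULL)
  rec
}

#' Resample a recording to a lower sampling rate
#'
#' Anti-aliased polyphase resampling (via `signal::resample`); the duration
#' is preserved to within one output sample.
#'
#' @param rec an [eeg_recording].
#' @param target_sfreq new sampling rate in Hz (must not exceed the current).
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_sfreq) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_sfreq <= 0) ms_stop("target sampling rate must be positive")
  if (target_sfreq > rec$sfreq)
    ms_stop("upsampling is not supported; target must be <= current rate")
  if (abs(target_sfreq - rec$sfreq) < 1e-12) return(rec)
  frac <- MASS_fractions(target_sfreq / rec$sfreq)
  out <- if (frac[1] == 1L) {
    # integer decimation: zero-phase Chebyshev low-pass (filtfilt) + pick
    t(apply(rec$data, 1L, function(x) signal::decimate(x, frac[2])))
  } else {
    t(apply(rec$data, 1L, function(x)
      signal::resample(x, p = frac[1], q = frac[2])))
  }
  n_target <- floor(ncol(rec$data) * target_sfreq / rec$sfreq)
  if (ncol(out) > n_target) out <- out[, seq_len(n_target), drop = FALSE]
  rec$data <- out
  dimnames(rec$data) <- list(rec$channel_names, NULL)
  rec$sfreq <- target_sfreq
  rec
}

# small rational approximation p/q of a ratio in (0, 1]
MASS_fractions <- function(ratio, max_den = 10000) {
  for (q in seq_len(max_den)) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  ms_stop("sampling-rate ratio has no small rational approximation")
}

# Perrin-style spherical spline matrix: g(cosine) truncated Legendre series
# with smoothing order m.
spline_g <- function(cosang, m = 4, terms = 50) {
  out <- matrix(0, nrow(cosang), ncol(cosang))
  # Legendre recurrence evaluated for the whole matrix at once
  Pnm1 <- matrix(1, nrow(cosang), ncol(cosang))
  Pn <- cosang
  for (n in seq_len(terms)) {
    out <- out + (2 * n + 1) / (n^m * (n + 1)^m) * Pn
    Pnp1 <- ((2 * n + 1) * cosang * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn
    Pn <- Pnp1
  }
  out / (4 * pi)
}

#' Interpolate bad channels with a 3D spherical spline
#'
#' Fits a Perrin-style spherical spline through the good channels of every
#' sample (with a zero-mean constraint and Tikhonov regularisation `lambda`)
#' and replaces the listed bad channels with the spline prediction. Good
#' channels are left untouched.
#'
#' @param rec an [eeg_recording] with a montage.
#' @param bad_channels character vector of channel names to replace.
#' @param m spline smoothing order (default 4).
#' @param terms number of Legendre terms (default 50).
#' @param lambda regularisation added to the diagonal (default 1e-5).
#' @return the recording with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad_channels, m = 4, terms = 50,
                                 lambda = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad_channels) == 0L) return(rec)
  if (is.null(rec$montage)) ms_stop("interpolation requires a montage")
  unknown <- setdiff(bad_channels, rec$channel_names)
  if (length(unknown))
    ms_stop(sprintf("unknown bad channel(s): %s", paste(unknown, collapse = ", ")))
  if (length(bad_channels) >= 0.2 * length(rec$channel_names))
    ms_stop("refusing to interpolate 20% or more of the channels")
  bad <- match(bad_channels, rec$channel_names)
  good <- setdiff(seq_along(rec$channel_names), bad)

  cos_gg <- tcrossprod(rec$montage[good, , drop = FALSE])
  cos_bg <- tcrossprod(rec$montage[bad, , drop = FALSE],
                       rec$montage[good, , drop = FALSE])
  G <- spline_g(pmin(pmax(cos_gg, -1), 1), m, terms) + diag(lambda, length(good))
  Gb <- spline_g(pmin(pmax(cos_bg, -1), 1), m, terms)
  # solve [G 1; 1' 0] [c; c0] = [v; 0] for all samples at once
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  rc <- rcond(A)
  if (rc < 1e-14)
    ms_stop(sprintf("singular spline system (rcond = %.2e)", rc))
  rhs <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  coefs <- sol[seq_along(good), , drop = FALSE]
  c0 <- sol[length(good) + 1L, ]
  rec$data[bad, ] <- Gb %*% coefs + rep(c0, each = length(bad))
  rec
}

#' ICA artifact-removal hook (no-op)
#'
#' Placeholder in the preprocessing chain where independent component
#' analysis would remove cardiac and oculomotor artefacts on real data.
#' Synthetic recordings contain no such artefacts, so the default
#' implementation returns its input unchanged with a warning on real data.
#'
#' @param rec an [eeg_recording].
#' @param fun optional function `rec -> rec` performing the actual cleaning.
#' @return the (possibly cleaned) recording.
#' @export
ica_hook <- function(rec, fun = NULL) {
  if (is.null(fun)) {
    message("ICA hook: no artifact-removal function supplied; data passed through")
    return(rec)
  }
  fun(rec)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: band-pass filter, resampling, ICA hook, spherical-spline
#' interpolation of bad channels, and common average reference. The order is
#' fixed; each applied stage is recorded in the returned recording's
#' `preprocessing` attribute.
#'
#' @param rec an [eeg_recording].
#' @param band numeric length-2 pass band in Hz.
#' @param target_sfreq output sampling rate in Hz (`NULL` = keep).
#' @param bad_channels channels to interpolate (default none).
#' @param crop optional `c(start_s, duration_s)` applied first.
#' @param m,terms,lambda spherical-spline settings.
#' @param ica optional ICA cleaning function for [ica_hook()].
#' @return the preprocessed, average-referenced recording.
#' @export
preprocess <- function(rec, band = c(1, 40), target_sfreq = 125,
                       bad_channels = character(0), crop = NULL,
                       m = 4, terms = 50, lambda = 1e-5, ica = NULL) {
  stages <- character(0)
  if (!is.null(crop)) {
    rec <- crop_recording(rec, crop[1], crop[2]); stages <- c(stages, "crop")
  }
  rec <- bandpass_filter(rec, band[1], band[2]); stages <- c(stages, "bandpass")
  if (!is.null(target_sfreq) && target_sfreq < rec$sfreq) {
    rec <- resample_recording(rec, target_sfreq); stages <- c(stages, "resample")
  }
  rec <- ica_hook(rec, ica); stages <- c(stages, "ica_hook")
  if (length(bad_channels)) {
    rec <- interpolate_channels(rec, bad_channels, m, terms, lambda)
    stages <- c(stages, "interpolate")
  }
  rec <- rereference_average(rec); stages <- c(stages, "average_reference")
  attr(rec, "preprocessing") <- stages
  rec
}
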