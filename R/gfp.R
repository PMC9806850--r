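#' Global field power of a recording
#'
#' GFP(t) is the spatial standard deviation of the scalp map at time t,
#' `sqrt(mean((v_i(t) - vbar(t))^2))`. Its local maxima are the moments of
#' highest topographic signal-to-noise and are where segmentation samples maps.
#'
#' @param rec an [eeg_recording]; a warning is issued if it is not
#'   average-referenced (GFP is reference-dependent otherwise).
#' @param min_separation_ms minimum spacing between retained GFP peaks.
#' @return object of class `gfp_series` with elements `values`,
#'   `peak_indices` and `sfreq`.
#' @export
compute_gfp <- function(rec, min_separation_ms = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) == 0L) ms_stop("empty recording")
  if (!identical(rec$reference, "average"))
    warning("recording is not average-referenced; GFP depends on the reference")
  centred <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  values <- sqrt(colMeans(centred^2))
  structure(list(values = values,
                 peak_indices = find_gfp_peaks(values, rec$sfreq,
                                               min_separation_ms),
                 sfreq = rec$sfreq),
            class = "gfp_series")
}

#' Local maxima of a GFP series
#'
#' Strict local maxima (endpoints excluded), greedily thinned in descending
#' GFP order so that retained peaks are at least `min_separation_ms` apart.
#' On a plateau the first plateau sample counts as the peak.
#'
#' @param values numeric GFP series (or a `gfp_series`).
#' @param sfreq sampling rate in Hz.
#' @param min_separation_ms minimum peak spacing in milliseconds.
#' @return integer vector of peak sample indices, strictly increasing.
#' @export
find_gfp_peaks <- function(values, sfreq, min_separation_ms = 10) {
  if (inherits(values, "gfp_series")) {
    sfreq <- values$sfreq
    values <- values$values
  }
  n <- length(values)
  if (n < 3L) return(integer(0))
  # plateau-aware strict maxima: rising into the sample, falling after the
  # plateau it starts
  rle_v <- rle(values)
  ends <- cumsum(rle_v$lengths)
  starts <- ends - rle_v$lengths + 1L
  k <- length(rle_v$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_pk <- rle_v$values[mid] > rle_v$values[mid - 1L] &
           rle_v$values[mid] > rle_v$values[mid + 1L]
  peaks <- starts[mid][is_pk]
  if (length(peaks) == 0L) return(integer(0))
  min_gap <- min_separation_ms * sfreq / 1000
  ord <- order(values[peaks], decreasing = TRUE)
  keep <- logical(length(peaks))
  taken <- numeric(0)
  for (i in ord) {
    if (all(abs(peaks[i] - taken) >= min_gap)) {
      keep[i] <- TRUE
      taken <- c(taken, peaks[i])
    }
  }
  sort(peaks[keep])
}

#' Spatial correlation between two scalp topographies
#'
#' Pearson correlation across channels of the mean-centred maps; with
#' `polarity_invariant = TRUE` (the resting-state convention) the absolute
#' value is returned, treating a map and its sign-flip as the same state.
#'
#' @param u,v numeric vectors of equal length (one voltage per channel).
#' @param polarity_invariant return `|r|` instead of signed r.
#' @return correlation in `[0, 1]` (or `[-1, 1]` when signed).
#' @export
spatial_correlation <- function(u, v, polarity_invariant = TRUE) {
  if (length(u) != length(v)) ms_stop("maps have different channel counts")
  u <- u - mean(u); v <- v - mean(v)
  su <- sqrt(sum(u^2)); sv <- sqrt(sum(v^2))
  if (su < 1e-15 || sv < 1e-15) ms_stop("zero-variance map")
  r <- sum(u * v) / (su * sv)
  if (polarity_invariant) abs(r) else r
}
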