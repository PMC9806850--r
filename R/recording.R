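#' Construct an EEG recording object
#'
#' The central container of the package: a channels x samples voltage matrix
#' (microvolts) with its sampling rate, channel names, optional unit-sphere
#' montage and reference state. All analysis functions take and return this
#' class; channel identity is matched by name downstream, never by position.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sfreq sampling rate in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param montage optional `n_channels x 3` unit-sphere coordinate matrix.
#' @param reference `"original"` or `"average"`.
#' @param subject_id optional subject identifier.
#' @param group optional group label (e.g. `"patient"`, `"control"`).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_names = rownames(data),
                          montage = NULL, reference = c("original", "average"),
                          subject_id = NA_character_, group = NA_character_) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (nrow(data) < 3L) ms_stop("an EEG recording needs at least 3 channels")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    ms_stop("sfreq must be a single positive number")
  if (is.null(channel_names)) channel_names <- sprintf("E%03d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    ms_stop("channel_names length must equal the number of data rows",
            class = "microstatr_structure_error")
  assert_finite_matrix(data, "recording data", channel_names)
  validate_montage(montage, nrow(data))
  dimnames(data) <- list(channel_names, NULL)
  if (!is.null(montage)) rownames(montage) <- channel_names
  structure(list(data = data, sfreq = sfreq, channel_names = channel_names,
                 montage = montage, reference = reference,
                 subject_id = subject_id, group = group),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$sfreq
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$data), ncol(x$data), dur, x$sfreq))
  cat(sprintf("  reference: %s | montage: %s | subject: %s | group: %s\n",
              x$reference, if (is.null(x$montage)) "none" else "unit sphere",
              x$subject_id, x$group))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so that
#' each column of the data matrix has zero mean. Idempotent; the global field
#' power of an already average-referenced recording is unchanged.
#'
#' @param rec an [eeg_recording].
#' @return the recording with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) ms_stop("average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec$reference <- "average"
  rec
}

#' Crop a recording in time
#'
#' @param rec an [eeg_recording].
#' @param start start time in seconds (0 = first sample).
#' @param duration duration in seconds; `NULL` keeps everything from `start`.
#' @return the cropped recording.
#' @export
crop_recording <- function(rec, start = 0, duration = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  i0 <- floor(start * rec$sfreq) + 1L
  i1 <- if (is.null(duration)) ncol(rec$data)
        else min(ncol(rec$data), i0 + floor(duration * rec$sfreq) - 1L)
  if (i0 < 1L || i0 > i1) ms_stop("crop window is empty or out of range")
  rec$data <- rec$data[, i0:i1, drop = FALSE]
  rec
}
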