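# Back-fitting: label every sample of the continuous EEG with its
# best-matching template and derive the four temporal parameters per class.
# Every sample is labelled (no correlation-threshold rejection); zero-variance
# samples inherit the previous label with corr = 0.

#' Label every sample of a recording with its best-matching template
#'
#' Per sample, the winning class maximises the (absolute, when polarity
#' invariance is on) spatial correlation with the template maps. Ties are
#' broken toward the previous sample's label, else toward the lowest class
#' index. Zero-variance samples inherit the previous label with correlation 0
#' (count reported in the `n_zero_variance` attribute).
#'
#' @param rec an [eeg_recording] (warned if not average-referenced).
#' @param templates a [template_set] with matching channels.
#' @param polarity_invariant compare by `|r|` (default) or signed r.
#' @return a [label_series].
#' @export
assign_labels <- function(rec, templates, polarity_invariant = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(templates, "template_set"))
  if (!identical(rec$channel_names, templates$channel_names)) {
    if (!setequal(rec$channel_names, templates$channel_names))
      ms_stop("recording and template channels differ",
              class = "microstatr_structure_error")
    ms_stop("recording and template channel order differs; reorder explicitly",
            class = "microstatr_structure_error")
  }
  if (!identical(rec$reference, "average"))
    warning("recording is not average-referenced; back-fitting assumes it is")
  X <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
  nrm <- sqrt(colSums(X^2))
  ok <- nrm > 1e-12
  Xn <- X
  Xn[, ok] <- sweep(X[, ok, drop = FALSE], 2L, nrm[ok], "/")
  C <- templates$maps %*% Xn                     # K x n_samples correlations
  if (polarity_invariant) C <- abs(C)
  K <- nrow(C)
  labels <- integer(ncol(C))
  corr <- numeric(ncol(C))
  prev <- 1L
  for (t in seq_len(ncol(C))) {
    if (!ok[t]) {
      labels[t] <- prev
      corr[t] <- 0
      next
    }
    ct <- C[, t]
    best <- max(ct)
    cand <- which(ct >= best - 1e-12)
    labels[t] <- if (prev %in% cand) prev else cand[1L]
    corr[t] <- ct[labels[t]]
    prev <- labels[t]
  }
  out <- label_series(labels, pmin(abs(corr), 1), rec$sfreq,
                      templates$class_labels)
  attr(out, "n_zero_variance") <- sum(!ok)
  out
}

#' Absorb label runs shorter than a duration threshold
#'
#' Each sample of a run shorter than `min_duration_ms` is reassigned to the
#' neighbouring run (previous or next) whose class has the higher correlation
#' at that sample. `min_duration_ms = 0` (the default throughout the package)
#' disables smoothing. The operation is idempotent at a fixed threshold.
#'
#' @param series a [label_series].
#' @param min_duration_ms minimum surviving run length in ms.
#' @param rec optional [eeg_recording]; when supplied with `templates` the
#'   reassignment uses exact per-sample correlations, otherwise the stored
#'   winning correlations decide.
#' @param templates optional [template_set] matching `rec`.
#' @return the smoothed [label_series].
#' @export
smooth_labels <- function(series, min_duration_ms = 0, rec = NULL,
                          templates = NULL) {
  stopifnot(inherits(series, "label_series"))
  if (min_duration_ms <= 0) return(series)
  min_len <- ceiling(min_duration_ms * series$sfreq / 1000)
  C <- NULL
  if (!is.null(rec) && !is.null(templates)) {
    X <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
    nrm <- pmax(sqrt(colSums(X^2)), 1e-12)
    C <- abs(templates$maps %*% sweep(X, 2L, nrm, "/"))
  }
  labels <- series$labels
  repeat {
    runs <- rle(labels)
    short <- which(runs$lengths < min_len)
    # interior short runs only; edge-truncated runs are left alone
    short <- short[short > 1L & short < length(runs$lengths)]
    if (length(short) == 0L) break
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    i <- short[which.min(runs$lengths[short])]   # shortest first
    left <- runs$values[i - 1L]
    right <- runs$values[i + 1L]
    for (t in starts[i]:ends[i]) {
      labels[t] <- if (is.null(C)) {
        if (t - starts[i] <= ends[i] - t) left else right
      } else if (C[left, t] >= C[right, t]) left else right
    }
  }
  series$labels <- labels
  series
}

#' Temporal parameters of each microstate class
#'
#' From a label series (and the recording + GFP series for GEV), computes per
#' class: time coverage `TC = 100 x #samples / n`, mean duration
#' `MD = mean run length x 1000 / sfreq` (edge-truncated runs included),
#' occurrence `occ = #runs / minutes`, and
#' `GEV_k = sum_{t labelled k} GFP_t^2 r_t^2 / sum_t GFP_t^2`. Classes with
#' no samples report 0 with `absent = TRUE`. By construction
#' `TC = occ x MD / 600` for every class and coverages sum to 100.
#'
#' @param series a [label_series].
#' @param gfp the matching `gfp_series` (from [compute_gfp()]); optional,
#'   required for GEV.
#' @param rec the labelled [eeg_recording]; optional, required for GEV.
#' @param templates the [template_set] used for labelling; optional,
#'   required for GEV.
#' @return data frame with one row per class: `class`, `gev`,
#'   `mean_duration_ms`, `time_coverage_pct`, `occurrence_per_min`, `absent`.
#' @export
compute_parameters <- function(series, gfp = NULL, rec = NULL,
                               templates = NULL) {
  stopifnot(inherits(series, "label_series"))
  n <- length(series$labels)
  K <- length(series$class_labels)
  if (!is.null(rec) && ncol(rec$data) != n)
    ms_stop("label series and recording lengths differ")
  runs <- label_runs(series$labels)
  duration_min <- n / series$sfreq / 60

  gev_k <- rep(NA_real_, K)
  if (!is.null(gfp) && !is.null(rec) && !is.null(templates)) {
    g2 <- gfp$values^2
    X <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
    nrm <- pmax(sqrt(colSums(X^2)), 1e-12)
    r <- (templates$maps %*% sweep(X, 2L, nrm, "/"))
    r_t <- r[cbind(series$labels, seq_len(n))]
    denom <- sum(g2)
    gev_k <- vapply(seq_len(K), function(k) {
      idx <- series$labels == k
      sum(g2[idx] * r_t[idx]^2) / denom
    }, numeric(1))
  }
  out <- data.frame(class = series$class_labels, gev = gev_k,
                    mean_duration_ms = 0, time_coverage_pct = 0,
                    occurrence_per_min = 0, absent = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    ln <- runs$length[runs$class == k]
    if (length(ln) == 0L) {
      out$absent[k] <- TRUE
      next
    }
    out$mean_duration_ms[k] <- mean(ln) * 1000 / series$sfreq
    out$time_coverage_pct[k] <- 100 * sum(ln) / n
    out$occurrence_per_min[k] <- length(ln) / duration_min
  }
  out
}

#' Back-fit a cohort of recordings against shared templates
#'
#' Labels every recording with the population template set and assembles the
#' per-subject, per-class parameter table used by the group statistics.
#' Failures are collected per subject and reported together rather than
#' aborting the cohort.
#'
#' @param recordings list of preprocessed [eeg_recording] objects.
#' @param templates the population [template_set].
#' @param min_duration_ms optional smoothing threshold (0 = off).
#' @param polarity_invariant passed to [assign_labels()].
#' @return data frame with one row per subject x class (`subject_id`,
#'   `group`, plus the [compute_parameters()] columns).
#' @export
backfit_cohort <- function(recordings, templates, min_duration_ms = 0,
                           polarity_invariant = TRUE) {
  rows <- vector("list", length(recordings))
  failures <- character(0)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    res <- tryCatch({
      series <- assign_labels(rec, templates, polarity_invariant)
      if (min_duration_ms > 0)
        series <- smooth_labels(series, min_duration_ms, rec, templates)
      gfp <- compute_gfp(rec)
      p <- compute_parameters(series, gfp, rec, templates)
      cbind(subject_id = rec$subject_id, group = rec$group, p,
            stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("%s: %s", rec$subject_id, conditionMessage(res)))
    } else rows[[i]] <- res
  }
  if (length(failures))
    ms_stop(paste0("back-fitting failed for ", length(failures), " subject(s):\n",
                   paste(failures, collapse = "\n")))
  do.call(rbind, rows)
}
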