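#' Fit microstate templates to a resting-state EEG recording
#'
#' The package's central fitting function. Computes the global field power
#' (GFP) series, extracts its local maxima, and clusters the peak topographies
#' with polarity-invariant [modified_kmeans()]. The number of maps is either
#' fixed (`k`) or chosen by the seven-criterion [meta_criterion()] over
#' `k_range`. The returned object supports `print`, `summary`, `coef`
#' (template matrix), `predict` (back-fitting onto a recording),
#' `residuals`, `plot` and `simulate` methods.
#'
#' @param x an [eeg_recording] (warned if not average-referenced).
#' @param k fixed number of maps; `NULL` selects it via the meta-criterion.
#' @param k_range candidate K values when `k` is `NULL`.
#' @param n_restarts,max_iter,tol [modified_kmeans()] settings.
#' @param min_separation_ms minimum GFP-peak spacing in ms.
#' @param seed integer seed (restarts and criterion fits).
#' @param ... reserved.
#' @return object of class `microstates`, extending `segmentation_result`
#'   with the GFP series, peak indices, the fitted recording and (when K was
#'   selected) the `meta_criterion_report`.
#' @examples
#' cfg <- synthetic_config(n_channels = 32, duration_s = 20)
#' mont <- build_spherical_montage(32)
#' tpl <- make_templates(mont, 4, seed = 7)
#' seq4 <- simulate_state_sequence(4, 2500, 125, seed = 7)
#' rec <- synthesize_recording(tpl, seq4$states, mont, cfg, seed = 7)
#' fit <- microstates(rec, k = 4, n_restarts = 5, seed = 7)
#' fit
#' @export
microstates <- function(x, k = NULL, k_range = 2:8, n_restarts = 20,
                        max_iter = 100, tol = 1e-7, min_separation_ms = 10,
                        seed = 1L, ...) {
  stopifnot(inherits(x, "eeg_recording"))
  gfp <- compute_gfp(x, min_separation_ms)
  peaks <- gfp$peak_indices
  k_min <- if (is.null(k)) max(k_range) else k
  if (length(peaks) < 10 * k_min)
    ms_stop(sprintf("too few GFP peaks (%d) for K = %d; need at least %d",
                    length(peaks), k_min, 10 * k_min))
  peak_maps <- t(x$data[, peaks, drop = FALSE])
  colnames(peak_maps) <- x$channel_names

  report <- NULL
  if (is.null(k)) {
    report <- meta_criterion(peak_maps, K_range = k_range,
                             n_restarts = n_restarts, max_iter = max_iter,
                             tol = tol, seed = seed)
    k <- report$meta_optimal_K
    fit <- report$fits[[as.character(k)]]
  } else {
    fit <- modified_kmeans(peak_maps, k, n_restarts = n_restarts,
                           max_iter = max_iter, tol = tol, seed = seed)
  }
  fit$templates$level <- "individual"
  out <- c(fit, list(gfp = gfp, peak_indices = peaks, recording = x,
                     meta_report = report, k = k, call = match.call()))
  class(out) <- c("microstates", "segmentation_result")
  out
}

#' @export
print.microstates <- function(x, ...) {
  cat(sprintf("Microstate segmentation (%s)\n", x$templates$level))
  cat(sprintf("  K = %d maps%s, %d GFP-peak topographies, GEV = %.3f\n",
              x$k, if (!is.null(x$meta_report)) " (meta-criterion)" else "",
              length(x$peak_indices), x$gev_total))
  invisible(x)
}

#' @export
summary.microstates <- function(object, ...) {
  tab <- data.frame(class = object$templates$class_labels,
                    gev = object$gev_per_class,
                    n_peak_maps = tabulate(object$assignment, object$k))
  out <- list(k = object$k, gev_total = object$gev_total, classes = tab,
              n_peaks = length(object$peak_indices),
              meta = object$meta_report)
  class(out) <- "summary.microstates"
  out
}

#' @export
print.summary.microstates <- function(x, ...) {
  cat(sprintf("Microstate fit: K = %d, total GEV at GFP peaks = %.3f (%d peaks)\n",
              x$k, x$gev_total, x$n_peaks))
  print(x$classes, row.names = FALSE)
  if (!is.null(x$meta)) {
    cat("Meta-criterion votes per validity index:\n")
    print(x$meta$optimal_k)
  }
  invisible(x)
}

#' @export
coef.microstates <- function(object, ...) object$templates$maps

#' @export
residuals.microstates <- function(object, ...) {
  peak_maps <- t(object$recording$data[, object$peak_indices, drop = FALSE])
  X <- centre_normalise(peak_maps)
  Th <- object$templates$maps
  centred <- peak_maps - rowMeans(peak_maps)
  proj <- rowSums(X$maps * Th[object$assignment, , drop = FALSE])
  centred - Th[object$assignment, , drop = FALSE] * (proj * X$norm)
}

#' Back-fit fitted templates onto a recording
#'
#' `predict` labels every sample of `newdata` (default: the recording the
#' model was fitted to) with the template of maximal absolute spatial
#' correlation — the back-fitting step of microstate analysis.
#'
#' @param object a `microstates` fit.
#' @param newdata an [eeg_recording]; default the training recording.
#' @param min_duration_ms optional temporal smoothing threshold (0 = off).
#' @param ... passed to [assign_labels()].
#' @return a [label_series].
#' @export
predict.microstates <- function(object, newdata = NULL, min_duration_ms = 0, ...) {
  rec <- newdata %||% object$recording
  series <- assign_labels(rec, object$templates, ...)
  if (min_duration_ms > 0) series <- smooth_labels(series, min_duration_ms)
  series
}

#' Simulate surrogate recordings from a microstate fit
#'
#' Generates semi-Markov surrogate EEG with the fitted templates and the
#' temporal parameters (per-class mean duration, occupancy) estimated by
#' back-fitting the training recording; the signal-to-noise ratio is matched
#' to the fit's explained variance at GFP peaks.
#'
#' @param object a `microstates` fit.
#' @param nsim number of surrogate recordings.
#' @param seed integer seed.
#' @param duration_s surrogate length (default: the training duration).
#' @param ... reserved.
#' @return list of [eeg_recording] objects.
#' @export
simulate.microstates <- function(object, nsim = 1, seed = 1L,
                                 duration_s = NULL, ...) {
  rec <- object$recording
  duration_s <- duration_s %||% (ncol(rec$data) / rec$sfreq)
  series <- predict(object)
  params <- compute_parameters(series, object$gfp, rec, object$templates)
  md <- pmax(params$mean_duration_ms, 1000 / rec$sfreq)
  snr <- max(object$gev_total / max(1 - object$gev_total, 1e-6), 0.1)
  cfg <- synthetic_config(n_channels = nrow(rec$data), sfreq = rec$sfreq,
                          duration_s = duration_s, mean_dwell_ms = md,
                          snr = snr)
  montage <- rec$montage %||% build_spherical_montage(nrow(rec$data))
  n <- round(duration_s * rec$sfreq)
  lapply(seq_len(nsim), function(i) {
    s <- simulate_state_sequence(object$k, n, rec$sfreq, mean_dwell_ms = md,
                                 seed = derive_seed(seed, paste0("sim", i)))
    synthesize_recording(object$templates, s$states, montage, cfg,
                         seed = derive_seed(seed, paste0("simrec", i)))
  })
}

#' Pool individual template sets into a group- or population-level set
#'
#' Concatenates the (unit-norm) template maps of several subjects and
#' re-clusters them with [modified_kmeans()] (fixed `k`) or
#' [meta_criterion()] (`k = NULL`), yielding the shared template set used
#' for back-fitting.
#'
#' @param template_sets list of [template_set] objects with identical
#'   channels.
#' @param k fixed number of group maps, or `NULL` for meta-criterion choice.
#' @param k_range candidate K values when `k` is `NULL`.
#' @param level `"group"` or `"population"` tag for the result.
#' @param n_restarts,max_iter,tol,seed clustering settings.
#' @return a `segmentation_result` whose `templates` carry the requested
#'   level (plus `meta_report` when K was selected).
#' @export
group_segmentation <- function(template_sets, k = NULL, k_range = 2:8,
                               level = c("group", "population"),
                               n_restarts = 50, max_iter = 100, tol = 1e-7,
                               seed = 1L) {
  level <- match.arg(level)
  if (length(template_sets) < 2L) ms_stop("need at least 2 template sets")
  chans <- lapply(template_sets, function(s) s$channel_names)
  if (!all(vapply(chans, identical, logical(1), y = chans[[1]])))
    ms_stop("template sets have mismatching channels",
            class = "microstatr_structure_error")
  pooled <- do.call(rbind, lapply(template_sets, function(s) s$maps))
  if (is.null(k)) {
    report <- meta_criterion(pooled, K_range = k_range, n_restarts = n_restarts,
                             max_iter = max_iter, tol = tol, seed = seed)
    fit <- report$fits[[as.character(report$meta_optimal_K)]]
    fit$meta_report <- report
  } else {
    fit <- modified_kmeans(pooled, k, n_restarts = n_restarts,
                           max_iter = max_iter, tol = tol, seed = seed,
                           channel_names = chans[[1]])
  }
  fit$templates$level <- level
  fit
}

#' Match two template sets by maximal absolute spatial correlation
#'
#' Finds the one-to-one assignment between the maps of two sets that
#' maximises the total absolute spatial correlation (exact search over
#' assignments; sets of different size leave the extra maps of the larger
#' set unmatched).
#'
#' @param set1,set2 [template_set] objects (or plain map matrices) with equal
#'   channel counts.
#' @return data frame with one row per matched pair: `index1`, `index2`,
#'   `label1`, `label2` and `abs_correlation`.
#' @export
match_templates <- function(set1, set2) {
  m1 <- if (inherits(set1, "template_set")) set1$maps else centre_normalise(as.matrix(set1))$maps
  m2 <- if (inherits(set2, "template_set")) set2$maps else centre_normalise(as.matrix(set2))$maps
  if (ncol(m1) != ncol(m2)) ms_stop("channel counts differ")
  l1 <- if (inherits(set1, "template_set")) set1$class_labels else as.character(seq_len(nrow(m1)))
  l2 <- if (inherits(set2, "template_set")) set2$class_labels else as.character(seq_len(nrow(m2)))
  R <- abs(tcrossprod(m1, m2))
  swap <- nrow(R) > ncol(R)
  if (swap) R <- t(R)
  n_small <- nrow(R); n_big <- ncol(R)
  if (choose(n_big, n_small) * factorial(n_small) > 5e5)
    ms_stop("template sets too large for exact matching")
  combs <- utils::combn(n_big, n_small, simplify = FALSE)
  perms <- all_permutations(n_small)
  best <- NULL; best_score <- -Inf
  for (cb in combs) for (p in perms) {
    cols <- cb[p]
    score <- sum(R[cbind(seq_len(n_small), cols)])
    if (score > best_score) { best_score <- score; best <- cols }
  }
  i_small <- seq_len(n_small); i_big <- best
  if (swap) { idx1 <- i_big; idx2 <- i_small } else { idx1 <- i_small; idx2 <- i_big }
  r <- abs(rowSums((if (swap) m1[idx1, , drop = FALSE] else m1[idx1, , drop = FALSE]) *
                     m2[idx2, , drop = FALSE]))
  data.frame(index1 = idx1, index2 = idx2,
             label1 = l1[idx1], label2 = l2[idx2],
             abs_correlation = r, stringsAsFactors = FALSE)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' Canonical microstate archetype maps
#'
#' Analytic stand-ins for the classes reported in the resting-state
#' literature, built on a given montage (+x right, +y anterior, +z vertex):
#' A = left-posterior to right-anterior gradient, B = right-posterior to
#' left-anterior, C = anterior-posterior, D = fronto-central focal map,
#' E = left-right, F = occipital-central focal map.
#'
#' @param montage electrode coordinates.
#' @return a [template_set] with class labels A-F.
#' @export
canonical_archetypes <- function(montage) {
  validate_montage(montage)
  bump <- function(center) {
    ang <- acos(pmin(pmax(montage %*% center, -1), 1))
    exp(-ang^2 / (2 * 0.6^2))
  }
  maps <- rbind(
    A = drop(montage %*% c(1, 1, 0)) / sqrt(2),
    B = drop(montage %*% c(-1, 1, 0)) / sqrt(2),
    C = drop(montage %*% c(0, 1, 0)),
    D = drop(bump(c(0, 0.5, 0.866))),
    E = drop(montage %*% c(1, 0, 0)),
    F = drop(bump(c(0, -0.766, 0.643))))
  template_set(maps, class_labels = c("A", "B", "C", "D", "E", "F"),
               level = "population", channel_names = rownames(montage))
}

#' Label a template set against the canonical A-F archetypes
#'
#' Renames the classes of `templates` after the best-matching canonical
#' archetype (by [match_templates()] on the montage's analytic maps).
#'
#' @param templates a [template_set].
#' @param montage electrode coordinates matching the templates.
#' @return the template set with class labels replaced by archetype letters.
#' @export
label_microstates <- function(templates, montage) {
  arch <- canonical_archetypes(montage)
  m <- match_templates(templates, arch)
  labs <- templates$class_labels
  labs[m$index1] <- arch$class_labels[m$index2]
  templates$class_labels <- labs
  rownames(templates$maps) <- labs
  templates
}

#' Plot a microstate fit
#'
#' `type = "maps"` draws each template as a colour-coded electrode layout
#' (azimuthal projection from the vertex, red positive / blue negative);
#' `type = "criteria"` plots the normalised meta-criterion score curves when
#' the number of maps was selected automatically.
#'
#' @param x a `microstates` fit.
#' @param type `"maps"` or `"criteria"`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.microstates <- function(x, type = c("maps", "criteria"), ...) {
  type <- match.arg(type)
  if (type == "criteria") {
    if (is.null(x$meta_report)) ms_stop("fit has no meta-criterion report")
    plot(x$meta_report)
    return(invisible(x))
  }
  montage <- x$recording$montage %||% build_spherical_montage(nrow(x$recording$data))
  K <- x$k
  old <- graphics::par(mfrow = c(1, K), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(old))
  theta <- acos(pmin(pmax(montage[, 3], -1), 1))
  px <- theta * montage[, 1] / pmax(sqrt(rowSums(montage[, 1:2]^2)), 1e-9)
  py <- theta * montage[, 2] / pmax(sqrt(rowSums(montage[, 1:2]^2)), 1e-9)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  for (k in seq_len(K)) {
    v <- x$templates$maps[k, ]
    col <- pal[round(50 * v / max(abs(v))) + 51]
    plot(px, py, pch = 21, bg = col, cex = 1.6, axes = FALSE, xlab = "", ylab = "",
         main = sprintf("%s (GEV %.2f)", x$templates$class_labels[k],
                        x$gev_per_class[k]), asp = 1)
    graphics::symbols(0, 0, circles = max(theta) * 1.05, inches = FALSE,
                      add = TRUE, fg = "grey40")
  }
  invisible(x)
}

#' @export
plot.meta_criterion_report <- function(x, ...) {
  s <- x$scores
  norm <- apply(s, 2L, function(v) {
    f <- is.finite(v)
    if (sum(f) < 2L) return(rep(NA_real_, length(v)))
    v[f] <- (v[f] - min(v[f])) / max(diff(range(v[f])), 1e-12)
    v
  })
  graphics::matplot(x$K_range, norm, type = "b", pch = 1:ncol(norm), lty = 1,
                    xlab = "number of maps K", ylab = "normalised criterion score",
                    main = sprintf("Meta-criterion (chosen K = %d)", x$meta_optimal_K))
  graphics::abline(v = x$meta_optimal_K, col = "grey60", lty = 2)
  graphics::legend("bottomright", colnames(s), pch = 1:ncol(norm),
                   col = 1:6, cex = 0.7, bty = "n")
  invisible(x)
}
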