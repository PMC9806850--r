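#' Construct a microstate template set
#'
#' A template set holds K scalp topographies, one per microstate class, each
#' stored zero-mean and unit L2 norm (polarity is a free sign). The `level`
#' records where in the two-level clustering hierarchy the set was estimated.
#'
#' @param maps K x n_channels numeric matrix; rows are centred and normalised.
#' @param class_labels character vector of K class names (default "M1", ...).
#' @param level `"individual"`, `"group"` or `"population"`.
#' @param channel_names channel names, one per column.
#' @return object of class `template_set`.
#' @export
template_set <- function(maps, class_labels = NULL,
                         level = c("individual", "group", "population"),
                         channel_names = colnames(maps)) {
  level <- match.arg(level)
  maps <- as.matrix(maps)
  if (nrow(maps) < 1L) ms_stop("a template set needs at least one map")
  assert_finite_matrix(t(maps), "template maps", channel_names)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < 1e-12)) ms_stop("a template map has zero variance")
  maps <- maps / nrm
  if (is.null(class_labels)) class_labels <- sprintf("M%d", seq_len(nrow(maps)))
  if (length(class_labels) != nrow(maps))
    ms_stop("class_labels length must equal the number of maps")
  if (is.null(channel_names)) channel_names <- sprintf("E%03d", seq_len(ncol(maps)))
  if (nrow(maps) > 1L) {
    r <- abs(tcrossprod(maps))
    diag(r) <- 0
    if (any(r > 1 - 1e-12))
      ms_stop("two template maps are perfectly correlated")
  }
  dimnames(maps) <- list(class_labels, channel_names)
  structure(list(maps = maps, class_labels = class_labels, level = level,
                 channel_names = channel_names),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d maps x %d channels (level: %s)\n",
              nrow(x$maps), ncol(x$maps), x$level))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a microstate label series
#'
#' Per-sample microstate class assignment produced by back-fitting, together
#' with the winning absolute spatial correlation at each sample.
#'
#' @param labels integer vector of class indices (1..K).
#' @param corr numeric vector in `[0, 1]`, same length as `labels`.
#' @param sfreq sampling rate in Hz.
#' @param class_labels class names indexed by `labels`.
#' @return object of class `label_series`.
#' @export
label_series <- function(labels, corr, sfreq, class_labels) {
  if (length(labels) != length(corr))
    ms_stop("labels and corr must have equal length")
  if (any(corr < -1e-9 | corr > 1 + 1e-9))
    ms_stop("corr values must lie in [0, 1]")
  structure(list(labels = as.integer(labels), corr = pmin(pmax(corr, 0), 1),
                 sfreq = sfreq, class_labels = class_labels),
            class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  cat(sprintf("<label_series> %d samples at %g Hz, %d classes\n",
              length(x$labels), x$sfreq, length(x$class_labels)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_labels),
                      labels = x$class_labels))
  print(round(100 * tab / length(x$labels), 1))
  invisible(x)
}

# Run-length view of a label series: data frame of (class, length) per run.
label_runs <- function(labels) {
  r <- rle(labels)
  data.frame(class = r$values, length = r$lengths)
}
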