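# Plain-text I/O. The delimited dialect is tab-separated UTF-8 with a
# '#'-prefixed key=value header block; montage rows are name:x,y,z triplets
# separated by ';'. Chosen so fixtures are diffable and language-agnostic.

write_header_block <- function(con, kv) {
  for (k in names(kv)) {
    v <- kv[[k]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) next
    writeLines(sprintf("# %s=%s", k, v), con)
  }
}

parse_header_block <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)=(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  kv
}

fmt_montage <- function(montage) {
  paste(sprintf("%s:%.17g,%.17g,%.17g", rownames(montage),
                montage[, 1], montage[, 2], montage[, 3]), collapse = ";")
}

parse_montage_field <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  nm <- sub(":.*$", "", parts)
  xyz <- t(vapply(strsplit(sub("^[^:]*:", "", parts), ",", fixed = TRUE),
                  function(v) as.numeric(v), numeric(3)))
  rownames(xyz) <- nm
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

read_numeric_body <- function(lines, path) {
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) ms_stop(sprintf("no data rows in %s", path),
                                  class = "microstatr_format_error")
  rows <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    ms_stop(sprintf("ragged rows in %s (widths %s)", path,
                    paste(unique(ncols), collapse = ",")),
            class = "microstatr_format_error")
  x <- suppressWarnings(vapply(rows, as.numeric, numeric(ncols[1])))
  x <- if (is.matrix(x)) t(x) else matrix(x, ncol = 1L)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    ms_stop(sprintf("non-numeric cell in %s at row %d, column %d",
                    path, bad[1], bad[2]),
            class = "microstatr_parse_error")
  }
  x
}

#' Read an EEG recording from disk
#'
#' Supports the package's tab-separated dialect (self-describing header with
#' sampling rate, units, channel names and montage) and 16-bit EDF. Values are
#' converted to microvolts on read. The channel order in the file is
#' authoritative; downstream functions match channels by name.
#'
#' @param path file to read.
#' @param format `"delimited"` or `"edf"`; default guesses from the extension.
#' @return an [eeg_recording] with `reference = "original"` unless the header
#'   says otherwise.
#' @export
read_recording <- function(path, format = c("auto", "delimited", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (!file.exists(path)) ms_stop(sprintf("file not found: %s", path))
  if (format == "edf") return(read_edf(path))

  lines <- readLines(path, encoding = "UTF-8")
  kv <- parse_header_block(lines)
  for (req in c("sfreq", "channels"))
    if (is.null(kv[[req]]))
      ms_stop(sprintf("missing required header field '%s' in %s", req, path),
              class = "microstatr_format_error")
  ch <- strsplit(kv$channels, ",", fixed = TRUE)[[1]]
  x <- read_numeric_body(lines, path)
  if (nrow(x) != length(ch))
    ms_stop(sprintf("%d data rows but %d channel names in %s",
                    nrow(x), length(ch), path),
            class = "microstatr_structure_error")
  unit_scale <- switch(kv$units %||% "uV", uV = 1, mV = 1e3, V = 1e6,
                       ms_stop(sprintf("unknown units '%s'", kv$units),
                               class = "microstatr_format_error"))
  montage <- if (!is.null(kv$montage)) parse_montage_field(kv$montage) else NULL
  if (!is.null(montage) && !identical(rownames(montage), ch))
    ms_stop("montage channel names do not match data channel names",
            class = "microstatr_structure_error")
  eeg_recording(x * unit_scale, sfreq = as.numeric(kv$sfreq), channel_names = ch,
                montage = montage,
                reference = kv$reference %||% "original",
                subject_id = kv$subject_id %||% NA_character_,
                group = kv$group %||% NA_character_)
}

#' Write an EEG recording to disk
#'
#' @param rec an [eeg_recording]; data must be finite.
#' @param path destination file.
#' @param format `"delimited"` or `"edf"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "delimited", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  assert_finite_matrix(rec$data, "recording data", rec$channel_names)
  if (format == "edf") return(write_edf(rec, path))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write_header_block(con, list(
    sfreq = format(rec$sfreq, digits = 17), units = "uV",
    reference = rec$reference, subject_id = rec$subject_id, group = rec$group,
    channels = paste(rec$channel_names, collapse = ","),
    montage = if (!is.null(rec$montage)) fmt_montage(rec$montage)))
  utils::write.table(format(rec$data, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a template set to a tab-separated file
#' @param templates a [template_set].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  stopifnot(inherits(templates, "template_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write_header_block(con, list(
    class_labels = paste(templates$class_labels, collapse = ","),
    level = templates$level,
    channels = paste(templates$channel_names, collapse = ",")))
  utils::write.table(format(templates$maps, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a template set written by [write_templates()]
#' @param path file to read.
#' @return a [template_set].
#' @export
read_templates <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  kv <- parse_header_block(lines)
  maps <- read_numeric_body(lines, path)
  ch <- strsplit(kv$channels, ",", fixed = TRUE)[[1]]
  if (ncol(maps) != length(ch))
    ms_stop("template width does not match channel header",
            class = "microstatr_structure_error")
  template_set(maps, class_labels = strsplit(kv$class_labels, ",")[[1]],
               level = kv$level %||% "individual", channel_names = ch)
}

#' Write a microstate label series to a tab-separated file
#' @param series a [label_series].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(series, path) {
  stopifnot(inherits(series, "label_series"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write_header_block(con, list(
    sfreq = format(series$sfreq, digits = 17),
    class_labels = paste(series$class_labels, collapse = ",")))
  utils::write.table(
    cbind(series$labels, format(series$corr, digits = 17, trim = TRUE)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label series written by [write_labels()]
#' @param path file to read.
#' @return a [label_series].
#' @export
read_labels <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  kv <- parse_header_block(lines)
  x <- read_numeric_body(lines, path)
  label_series(labels = as.integer(x[, 1]), corr = x[, 2],
               sfreq = as.numeric(kv$sfreq),
               class_labels = strsplit(kv$class_labels, ",")[[1]])
}

#' Write a microstate parameter table (one row per subject x class)
#' @param params data frame as returned by [compute_parameters()] or
#'   [backfit_cohort()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  utils::write.table(params, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a parameter table written by [write_parameters()]
#' @param path file to read.
#' @return data frame.
#' @export
read_parameters <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a covariate table (CSV, one row per subject)
#'
#' Expects a `subject_id` column (unique) and a `group` column (non-missing);
#' remaining columns are numeric covariates such as disease duration, EDSS,
#' annual relapse rate or cognitive T scores.
#'
#' @param path CSV file.
#' @return data frame keyed by `subject_id`.
#' @export
read_covariates <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(x)))
    ms_stop("covariate table needs 'subject_id' and 'group' columns",
            class = "microstatr_format_error")
  if (anyDuplicated(x$subject_id))
    ms_stop("duplicate subject_id in covariate table",
            class = "microstatr_structure_error")
  if (any(is.na(x$group)))
    ms_stop("missing group label in covariate table",
            class = "microstatr_structure_error")
  x
}

#' Write a covariate table as CSV
#' @param covariates data frame with `subject_id` and `group` columns.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}
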