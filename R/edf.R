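# Minimal EDF (European Data Format) codec: 16-bit integer samples with
# per-channel physical scaling. Covers continuous multichannel recordings
# only — no annotations, events or discontinuous records. The physical range
# is set per channel to +/- 8x the channel's maximum absolute value so the
# quantization step stays below max|x| / 4096.

pad_ascii <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  formatC(s, width = -width, flag = " ")
}

num_field <- function(x, width) pad_ascii(formatC(x, format = "g", digits = width - 2), width)

write_edf <- function(rec, path) {
  x <- rec$data
  nch <- nrow(x); nsamp <- ncol(x)
  # one-second records when the duration is a whole number of integer-rate
  # seconds, otherwise a single record spanning the file
  if (rec$sfreq == round(rec$sfreq) && nsamp %% rec$sfreq == 0) {
    spr <- as.integer(rec$sfreq); nrec <- nsamp %/% spr; dur <- 1
  } else {
    spr <- nsamp; nrec <- 1L; dur <- nsamp / rec$sfreq
  }
  pmax_ch <- pmax(8 * apply(abs(x), 1L, max), .Machine$double.eps)
  dmin <- -32767L; dmax <- 32767L
  scale <- (2 * pmax_ch) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    pad_ascii("0", 8),
    pad_ascii(sprintf("subject %s", rec$subject_id), 80),
    pad_ascii(sprintf("microstatr group=%s ref=%s", rec$group, rec$reference), 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(as.character(256L * (1L + nch)), 8),
    pad_ascii("", 44),
    pad_ascii(as.character(nrec), 8),
    num_field(dur, 8),
    pad_ascii(as.character(nch), 4))
  writeChar(paste(hdr, collapse = ""), con, eos = NULL)
  sig <- paste(c(
    vapply(rec$channel_names, pad_ascii, "", width = 16),
    rep(pad_ascii("", 80), nch),
    rep(pad_ascii("uV", 8), nch),
    vapply(-pmax_ch, num_field, "", width = 8),
    vapply(pmax_ch, num_field, "", width = 8),
    rep(pad_ascii(as.character(dmin), 8), nch),
    rep(pad_ascii(as.character(dmax), 8), nch),
    rep(pad_ascii("", 80), nch),
    rep(pad_ascii(as.character(spr), 8), nch),
    rep(pad_ascii("", 32), nch)), collapse = "")
  writeChar(sig, con, eos = NULL)

  # EDF stores the header's printed physical range; quantize against the
  # parsed-back values so read(write(x)) hits the nearest representable level
  pmax_rt <- as.numeric(num_field(pmax_ch, 8))
  pmin_rt <- as.numeric(num_field(-pmax_ch, 8))
  scale_rt <- (pmax_rt - pmin_rt) / (dmax - dmin)
  dig <- round(sweep(sweep(x, 1L, (pmax_rt + pmin_rt) / 2, "-"), 1L, scale_rt, "/"))
  dig[dig > dmax] <- dmax; dig[dig < dmin] <- dmin
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  patient <- trimws(rd(80))
  recording <- trimws(rd(80))
  rd(8); rd(8)                            # date, time
  as.numeric(rd(8))                       # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(nch), function(i) rd(16), ""))
  vapply(seq_len(nch), function(i) rd(80), "")   # transducer
  vapply(seq_len(nch), function(i) rd(8), "")    # physical dimension
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  vapply(seq_len(nch), function(i) rd(80), "")   # prefiltering
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  vapply(seq_len(nch), function(i) rd(32), "")
  if (length(unique(spr)) != 1L)
    ms_stop("EDF with per-channel sampling rates is not supported",
            class = "microstatr_format_error")
  spr <- spr[1]
  x <- matrix(0, nrow = nch, ncol = nrec * spr)
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = nch * spr, size = 2L, signed = TRUE,
                   endian = "little")
    x[, ((r - 1L) * spr + 1L):(r * spr)] <-
      t(matrix(raw, nrow = spr, ncol = nch))
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  x <- sweep(sweep(x, 1L, scale, "*"), 1L, (pmax + pmin) / 2, "+")
  subj <- sub("^subject\\s+", "", patient)
  if (identical(subj, "NA")) subj <- NA_character_
  grp <- if (grepl("group=", recording))
    sub("^.*group=(\\S+).*$", "\\1", recording) else NA_character_
  ref <- if (grepl("ref=average", recording)) "average" else "original"
  eeg_recording(x, sfreq = spr / dur, channel_names = labels,
                reference = ref, subject_id = subj,
                group = if (identical(grp, "NA")) NA_character_ else grp)
}
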