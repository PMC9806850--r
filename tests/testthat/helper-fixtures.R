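# Shared fixture builders: everything is generated in code at test time.

fix_montage <- function(n = 32) build_spherical_montage(n)

fix_templates <- function(n_ch = 32, K = 4, seed = 7) {
  make_templates(fix_montage(n_ch), K, seed = seed)
}

# Small synthetic recording with known generative structure.
fix_recording <- function(n_ch = 32, K = 4, duration_s = 20, sfreq = 125,
                          snr = 2, seed = 7, polarity_flips = TRUE) {
  cfg <- synthetic_config(n_channels = n_ch, sfreq = sfreq,
                          duration_s = duration_s, snr = snr,
                          polarity_flips = polarity_flips, seed = seed)
  mont <- fix_montage(n_ch)
  tpl <- make_templates(mont, K, seed = seed)
  s <- simulate_state_sequence(K, round(duration_s * sfreq), sfreq, seed = seed)
  rec <- synthesize_recording(tpl, s$states, mont, cfg, seed = seed)
  list(rec = rec, templates = tpl, states = s$states, realized = s$realized,
       montage = mont, config = cfg)
}

# Noiseless recording whose every sample is exactly a (scaled, signed) template.
fix_exact_recording <- function(n_ch = 16, K = 3, n = 300, sfreq = 125,
                                seed = 3) {
  mont <- fix_montage(n_ch)
  tpl <- make_templates(mont, K, seed = seed)
  states <- rep(seq_len(K), each = 10, length.out = n)
  amp <- 4 + 2 * sin(seq_len(n) / 7)
  data <- t(tpl$maps[states, , drop = FALSE]) * rep(amp, each = n_ch)
  rec <- eeg_recording(data, sfreq, channel_names = rownames(mont),
                       montage = mont, reference = "average")
  list(rec = rec, templates = tpl, states = states, amp = amp)
}

# Exhaustive-search oracle: best GEV over all 2-cluster partitions of maps,
# templates = dominant eigenvector of the GFP^2-weighted scatter per part.
oracle_best_gev_k2 <- function(maps) {
  M <- nrow(maps)
  gfp <- sqrt(rowMeans((maps - rowMeans(maps))^2))
  w2 <- gfp^2
  X <- maps - rowMeans(maps)
  X <- X / sqrt(rowSums(X^2))
  eig1 <- function(idx) {
    S <- crossprod(X[idx, , drop = FALSE] * sqrt(w2[idx]))
    v <- eigen(S, symmetric = TRUE)$vectors[, 1]
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }
  best <- -Inf
  for (code in 0:(2^(M - 1) - 1)) {     # map 1 fixed in cluster 1
    part <- c(1L, as.integer(intToBits(code))[seq_len(M - 1)] + 1L)
    if (length(unique(part)) < 2L) next
    t1 <- eig1(which(part == 1L)); t2 <- eig1(which(part == 2L))
    r2 <- cbind((X %*% t1)^2, (X %*% t2)^2)
    gev <- sum(w2 * r2[cbind(seq_len(M), part)]) / sum(w2)
    if (gev > best) best <- gev
  }
  best
}
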