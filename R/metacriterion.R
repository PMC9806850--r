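# Choice of the number of microstate maps: seven cluster-validity indices,
# each adapted to the polarity-invariant correlation distance d = 1 - r^2,
# combined by taking the median of the per-criterion optimal K (ties broken
# toward the smaller K). The index set (Krzanowski-Lai, silhouette, inverted
# Davies-Bouldin, point-biserial, Dunn, Goodman-Kruskal gamma, and the
# cross-validation criterion) is a documented stand-in for "maximally
# independent measures" meta-criteria used in the microstate literature.

pairwise_d <- function(X) {
  r2 <- tcrossprod(X)^2
  d <- 1 - r2
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

crit_silhouette <- function(D, assign_vec, K) {
  M <- nrow(D)
  sizes <- tabulate(assign_vec, K)
  ind <- matrix(0, M, K)
  ind[cbind(seq_len(M), assign_vec)] <- 1
  sums <- D %*% ind                       # M x K: total distance to each cluster
  a <- sums[cbind(seq_len(M), assign_vec)] / pmax(sizes[assign_vec] - 1, 1)
  mean_to <- sweep(sums, 2L, pmax(sizes, 1), "/")
  mean_to[cbind(seq_len(M), assign_vec)] <- Inf
  b <- apply(mean_to, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[assign_vec] == 1L] <- 0
  mean(s)
}

crit_davies_bouldin_inv <- function(X, templ, assign_vec, K) {
  d_to_templ <- 1 - tcrossprod(X, templ)^2
  S <- vapply(seq_len(K), function(k) mean(d_to_templ[assign_vec == k, k]),
              numeric(1))
  Mkl <- pairwise_d(templ)
  R <- outer(S, S, "+") / pmax(Mkl, 1e-12)
  diag(R) <- -Inf
  db <- mean(apply(R, 1L, max))
  1 / max(db, 1e-12)
}

crit_point_biserial <- function(D, assign_vec) {
  M <- nrow(D)
  up <- upper.tri(D)
  dvec <- D[up]
  same <- (outer(assign_vec, assign_vec, "=="))[up]
  nw <- as.numeric(sum(same)); nb <- as.numeric(sum(!same)); nt <- nw + nb
  if (nw == 0L || nb == 0L) return(-Inf)
  (mean(dvec[!same]) - mean(dvec[same])) * sqrt(nw * nb / nt^2) / stats::sd(dvec)
}

crit_dunn <- function(D, assign_vec) {
  same <- outer(assign_vec, assign_vec, "==")
  diag(same) <- NA
  intra <- suppressWarnings(max(D[same & !is.na(same)], 0))
  inter <- min(D[!same & !is.na(same)])
  inter / max(intra, 1e-12)
}

crit_gamma <- function(D, assign_vec) {
  up <- upper.tri(D)
  dvec <- D[up]
  same <- (outer(assign_vec, assign_vec, "=="))[up]
  w <- dvec[same]; b <- sort(dvec[!same])
  if (length(w) == 0L || length(b) == 0L) return(-Inf)
  n_lt <- findInterval(w, b, left.open = TRUE)   # between-distances < w
  n_le <- findInterval(w, b)                     # between-distances <= w
  splus <- sum(as.numeric(length(b) - n_le))     # concordant: w < b
  sminus <- sum(as.numeric(n_lt))                # discordant: w > b
  (splus - sminus) / max(splus + sminus, 1)
}

# Pascual-Marqui style predictive-residual criterion (lower is better; the
# returned value is negated so that all seven criteria are maximised).
crit_cv_neg <- function(X, templ, assign_vec, n_ch, K) {
  r2 <- tcrossprod(X, templ)^2
  best <- r2[cbind(seq_len(nrow(X)), assign_vec)]
  sigma2 <- sum(1 - best) / (nrow(X) * (n_ch - 1))
  cv <- sigma2 * ((n_ch - 1) / (n_ch - 1 - K))^2
  -cv
}

# Krzanowski-Lai from the within-dispersion curve W(K); defined on interior Ks.
kl_curve <- function(Ks, W, p) {
  diffs <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)) {
    if (i == 1L) next
    diffs[i] <- (Ks[i - 1])^(2 / p) * W[i - 1] - (Ks[i])^(2 / p) * W[i]
  }
  kl <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)) {
    if (i > 1L && i < length(Ks) && is.finite(diffs[i]) && abs(diffs[i + 1]) > 1e-15)
      kl[i] <- abs(diffs[i]) / abs(diffs[i + 1])
  }
  kl
}

#' Select the number of microstate maps by a multi-criterion vote
#'
#' Runs [modified_kmeans()] for every K in `K_range` and scores each solution
#' with seven cluster-validity criteria adapted to the polarity-invariant
#' correlation distance `d = 1 - r^2`. The meta-choice is the median of the
#' per-criterion optimal Ks, ties broken toward the smaller K. When the
#' criteria disagree widely (fewer than half within one unit of the median)
#' the report is flagged and a warning raised — a sign the data carry no
#' stable cluster structure.
#'
#' @param maps M x n_channels matrix of topographies (typically GFP-peak maps).
#' @param K_range candidate numbers of clusters (default 2:8).
#' @param n_restarts,max_iter,tol passed to [modified_kmeans()].
#' @param seed integer seed.
#' @param max_maps pairwise criteria are computed on at most this many maps
#'   (deterministic even thinning) to bound the M x M distance matrix.
#' @return object of class `meta_criterion_report`: criterion score curves,
#'   per-criterion optimum, `meta_optimal_K`, the fitted
#'   [modified_kmeans()] results per K, and a concordance flag.
#' @export
meta_criterion <- function(maps, K_range = 2:8, n_restarts = 20, max_iter = 100,
                           tol = 1e-7, seed = 1L, max_maps = 3000) {
  maps <- as.matrix(maps)
  K_range <- sort(unique(as.integer(K_range)))
  M <- nrow(maps)
  if (length(K_range) < 1L || any(K_range < 1L))
    ms_stop("degenerate K_range")
  if (max(K_range) > M / 2)
    ms_stop("max(K_range) must be at most half the number of maps")
  n_ch <- ncol(maps)

  fits <- lapply(K_range, function(K)
    modified_kmeans(maps, K, n_restarts = n_restarts, max_iter = max_iter,
                    tol = tol, seed = derive_seed(seed, paste0("metaK", K))))
  names(fits) <- as.character(K_range)

  sub <- if (M > max_maps) round(seq(1L, M, length.out = max_maps)) else seq_len(M)
  Xs <- centre_normalise(maps[sub, , drop = FALSE])$maps
  D <- pairwise_d(Xs)
  X_all <- centre_normalise(maps)$maps

  crit_names <- c("krzanowski_lai", "silhouette", "davies_bouldin_inv",
                  "point_biserial", "dunn", "gamma", "cv")
  scores <- matrix(NA_real_, nrow = length(K_range), ncol = length(crit_names),
                   dimnames = list(as.character(K_range), crit_names))
  W <- numeric(length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- fits[[i]]
    templ <- fit$templates$maps
    asg <- fit$assignment
    asg_sub <- asg[sub]
    W[i] <- sum(1 - fit$map_r2)
    if (length(unique(asg_sub)) == K && K >= 2L) {
      scores[i, "silhouette"] <- crit_silhouette(D, asg_sub, K)
      scores[i, "davies_bouldin_inv"] <- crit_davies_bouldin_inv(Xs, templ, asg_sub, K)
      scores[i, "point_biserial"] <- crit_point_biserial(D, asg_sub)
      scores[i, "dunn"] <- crit_dunn(D, asg_sub)
      scores[i, "gamma"] <- crit_gamma(D, asg_sub)
    }
    scores[i, "cv"] <- crit_cv_neg(X_all, templ, asg, n_ch, K)
  }
  scores[, "krzanowski_lai"] <- kl_curve(K_range, W, p = n_ch - 1)

  opt_k <- vapply(crit_names, function(cn) {
    s <- scores[, cn]
    if (all(!is.finite(s))) return(NA_integer_)
    K_range[which.max(ifelse(is.finite(s), s, -Inf))]
  }, integer(1))
  votes <- sort(opt_k[!is.na(opt_k)])
  if (length(votes) == 0L) votes <- K_range[1]
  meta_k <- votes[floor((length(votes) + 1) / 2)]   # lower median: ties downward

  concordant <- length(votes) < 2L || stats::IQR(votes) <= 1
  if (!concordant)
    warning("cluster-validity criteria are non-concordant; no stable optimum")

  structure(list(K_range = K_range, scores = scores, optimal_k = opt_k,
                 meta_optimal_K = as.integer(meta_k), concordant = concordant,
                 fits = fits, W = W, seed = seed),
            class = "meta_criterion_report")
}

#' @export
print.meta_criterion_report <- function(x, ...) {
  cat(sprintf("<meta_criterion_report> K range %d..%d, meta-optimal K = %d%s\n",
              min(x$K_range), max(x$K_range), x$meta_optimal_K,
              if (x$concordant) "" else " (criteria non-concordant)"))
  print(x$optimal_k)
  invisible(x)
}
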