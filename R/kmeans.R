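# Polarity-invariant modified k-means over scalp topographies.
#
# Maps are centred and L2-normalised; similarity is squared spatial
# correlation, so a map and its sign-flip are equivalent. The template update
# is the dominant eigenvector of the GFP^2-weighted scatter of the assigned
# maps, which makes each full iteration a coordinate ascent on GEV (the
# GFP^2-weighted explained variance) — GEV is therefore non-decreasing across
# iterations within a run, and the invariant is asserted.

centre_normalise <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  keep_ok <- nrm > 1e-12
  maps[keep_ok, ] <- maps[keep_ok, , drop = FALSE] / nrm[keep_ok]
  list(maps = maps, norm = nrm, ok = keep_ok)
}

dominant_eigvec <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1L]
  v <- v - mean(v)              # re-centre (average reference) and renormalise
  v / sqrt(sum(v^2))
}

kmeans_single_run <- function(X, w2, K, init_idx, max_iter, tol) {
  M <- nrow(X)
  templ <- X[init_idx, , drop = FALSE]
  gev_prev <- -Inf
  sum_w2 <- sum(w2)
  assign_vec <- integer(M)
  gev_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    r2 <- tcrossprod(X, templ)^2                    # M x K squared correlations
    assign_vec <- max.col(r2, ties.method = "first")
    best_r2 <- r2[cbind(seq_len(M), assign_vec)]
    # empty-cluster policy: reseed from the worst-explained map
    for (k in seq_len(K)) {
      if (!any(assign_vec == k)) {
        worst <- which.min(best_r2)
        assign_vec[worst] <- k
        best_r2[worst] <- 1
        templ[k, ] <- X[worst, ]
      }
    }
    gev <- sum(w2 * best_r2) / sum_w2
    gev_trace <- c(gev_trace, gev)
    if (gev < gev_prev - 1e-12)
      ms_stop("internal error: GEV decreased within a k-means run")
    if (gev - gev_prev < tol && iter > 1L) break
    gev_prev <- gev
    for (k in seq_len(K)) {
      idx <- which(assign_vec == k)
      Xk <- X[idx, , drop = FALSE] * sqrt(w2[idx])
      templ[k, ] <- dominant_eigvec(crossprod(Xk))
    }
  }
  # final consistent assignment under the final templates
  r2 <- tcrossprod(X, templ)^2
  assign_vec <- max.col(r2, ties.method = "first")
  best_r2 <- r2[cbind(seq_len(M), assign_vec)]
  gev <- sum(w2 * best_r2) / sum_w2
  list(templates = templ, assignment = assign_vec, gev = gev,
       r2 = best_r2, n_iterations = iter, gev_trace = gev_trace)
}

#' Modified k-means clustering of scalp topographies
#'
#' Clusters a set of maps (typically GFP-peak topographies) into K classes
#' using squared spatial correlation as similarity and an eigenvector-based
#' template update, making the procedure polarity-invariant. The best of
#' `n_restarts` random initialisations (by GEV) is returned.
#'
#' GEV (global explained variance) is the GFP^2-weighted mean of the squared
#' correlation between each map and its assigned template:
#' `GEV = sum_p GFP_p^2 r_p^2 / sum_p GFP_p^2`.
#'
#' @param maps M x n_channels matrix of topographies (rows are centred and
#'   normalised internally; each row's GFP becomes its GEV weight).
#' @param K number of clusters, `K <= M`.
#' @param n_restarts random restarts (default 100).
#' @param max_iter maximum iterations per restart.
#' @param tol convergence threshold on the GEV increase.
#' @param seed integer seed controlling the restarts.
#' @param channel_names optional channel names for the returned templates.
#' @return object of class `segmentation_result`: a [template_set], the total
#'   and per-class GEV, per-map cluster assignment, iteration count and the
#'   GEV of every restart.
#' @export
modified_kmeans <- function(maps, K, n_restarts = 100, max_iter = 300,
                            tol = 1e-7, seed = 1L,
                            channel_names = colnames(maps)) {
  maps <- as.matrix(maps)
  M <- nrow(maps)
  if (M < K) ms_stop(sprintf("need at least K=%d maps, got %d", K, M))
  gfp_w <- sqrt(rowMeans((maps - rowMeans(maps))^2))
  cn <- centre_normalise(maps)
  if (!all(cn$ok)) ms_stop("input contains zero-variance maps")
  X <- cn$maps
  w2 <- gfp_w^2
  if (all(w2 < 1e-30)) w2 <- rep(1, M)

  # k-means++-style seeding in the polarity-invariant correlation distance:
  # after a random first template, each next one is drawn with probability
  # proportional to 1 - max r^2 against those already chosen, so small but
  # distinct clusters (e.g. a map carried by a few subjects) are reliably
  # represented among the initial templates.
  inits <- with_seed(derive_seed(seed, "kmeans-init"), {
    lapply(seq_len(n_restarts), function(i) {
      idx <- integer(K)
      idx[1] <- sample.int(M, 1L)
      if (K > 1L) {
        d2 <- 1 - drop(X %*% X[idx[1], ])^2
        for (k in 2:K) {
          d2[d2 < 1e-12] <- 0
          idx[k] <- if (sum(d2) <= 0) sample.int(M, 1L)
                    else sample.int(M, 1L, prob = d2)
          d2 <- pmin(d2, 1 - drop(X %*% X[idx[k], ])^2)
        }
      }
      idx
    })
  })
  best <- NULL
  restart_scores <- numeric(n_restarts)
  for (i in seq_len(n_restarts)) {
    run <- kmeans_single_run(X, w2, K, inits[[i]], max_iter, tol)
    restart_scores[i] <- run$gev
    if (is.null(best) || run$gev > best$gev + 1e-15) best <- run
  }

  gev_per_class <- vapply(seq_len(K), function(k) {
    idx <- best$assignment == k
    sum(w2[idx] * best$r2[idx]) / sum(w2)
  }, numeric(1))
  templates <- template_set(best$templates, channel_names = channel_names)
  structure(list(templates = templates,
                 gev_total = best$gev,
                 gev_per_class = gev_per_class,
                 assignment = best$assignment,
                 map_r2 = best$r2,
                 map_gfp = gfp_w,
                 n_iterations = best$n_iterations,
                 gev_trace = best$gev_trace,
                 seed = seed,
                 restart_scores = restart_scores),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> K = %d, GEV = %.4f (%d maps, %d restarts)\n",
              nrow(x$templates$maps), x$gev_total, length(x$assignment),
              length(x$restart_scores)))
  invisible(x)
}

# GEV of a labelled set of maps against fixed templates (used by oracles,
# back-fitting and the meta-criterion).
gev_of_assignment <- function(maps, templates, assignment) {
  gfp_w <- sqrt(rowMeans((maps - rowMeans(maps))^2))
  cn <- centre_normalise(maps)
  Th <- centre_normalise(templates)$maps
  r2 <- tcrossprod(cn$maps, Th)^2
  w2 <- gfp_w^2
  sum(w2 * r2[cbind(seq_len(nrow(maps)), assignment)]) / sum(w2)
}
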