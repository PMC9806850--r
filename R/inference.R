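# Group-level statistics: topographic permutation test (TANOVA), mixed-design
# repeated-measures ANOVA with Bonferroni post hoc contrasts, Pearson
# correlations, and SPSS-style stepwise multiple linear regression with VIF.

#' Global dissimilarity between two scalp maps
#'
#' `DISS = GFP(u/GFP(u) - v/GFP(v))`, the global field power of the
#' difference between the two GFP-normalised maps; ranges from 0 (identical
#' topographies up to scale) to 2 (sign-flipped). Satisfies
#' `DISS^2 = 2 (1 - r)` with r the spatial correlation.
#'
#' @param u,v numeric vectors (one voltage per channel), average-referenced.
#' @return dissimilarity in `[0, 2]`.
#' @export
dissimilarity <- function(u, v) {
  if (length(u) != length(v)) ms_stop("maps have different channel counts")
  u <- u - mean(u); v <- v - mean(v)
  gu <- sqrt(mean(u^2)); gv <- sqrt(mean(v^2))
  if (gu < 1e-15 || gv < 1e-15) ms_stop("zero-GFP map")
  sqrt(mean((u / gu - v / gv)^2))
}

#' Topographic ANOVA (TANOVA) permutation test
#'
#' Tests whether two groups differ in mean scalp topography. The statistic is
#' the global dissimilarity between the two group-mean maps (each subject map
#' GFP-normalised first); the null distribution is built by permuting subject
#' group labels. The add-one estimator
#' `p = (1 + #{perm >= observed}) / (1 + n_permutations)` avoids p = 0.
#'
#' @param groupA_maps,groupB_maps subject x channel matrices of per-subject
#'   mean maps (>= 2 rows each).
#' @param n_permutations number of label permutations (default 5000).
#' @param seed integer seed.
#' @return object of class `tanova_result` with `observed_diss`,
#'   `permutation_diss`, `p_value`, `n_permutations`, `seed`.
#' @export
tanova <- function(groupA_maps, groupB_maps, n_permutations = 5000, seed = 1L) {
  A <- as.matrix(groupA_maps); B <- as.matrix(groupB_maps)
  if (nrow(A) < 2L || nrow(B) < 2L) ms_stop("each group needs >= 2 subjects")
  if (ncol(A) != ncol(B)) ms_stop("channel counts differ")
  norm_gfp <- function(M) {
    M <- M - rowMeans(M)
    g <- sqrt(rowMeans(M^2))
    if (any(g < 1e-15)) ms_stop("zero-GFP map")
    M / g
  }
  X <- rbind(norm_gfp(A), norm_gfp(B))
  nA <- nrow(A); n <- nrow(X)
  stat <- function(idxA) {
    mA <- colMeans(X[idxA, , drop = FALSE])
    mB <- colMeans(X[-idxA, , drop = FALSE])
    dm <- (mA - mean(mA)) / max(sqrt(mean((mA - mean(mA))^2)), 1e-15) -
          (mB - mean(mB)) / max(sqrt(mean((mB - mean(mB))^2)), 1e-15)
    sqrt(mean(dm^2))
  }
  observed <- stat(seq_len(nA))
  perm <- with_seed(derive_seed(seed, "tanova"), {
    vapply(seq_len(n_permutations),
           function(i) stat(sample.int(n, nA)), numeric(1))
  })
  p <- (1 + sum(perm >= observed)) / (1 + n_permutations)
  structure(list(observed_diss = observed, permutation_diss = perm,
                 p_value = p, n_permutations = n_permutations, seed = seed),
            class = "tanova_result")
}

#' @export
print.tanova_result <- function(x, ...) {
  cat(sprintf("TANOVA: observed DISS = %.4f, p = %.4g (%d permutations)\n",
              x$observed_diss, x$p_value, x$n_permutations))
  invisible(x)
}

#' Mixed-design repeated-measures ANOVA with per-class post hoc contrasts
#'
#' Two-way ANOVA with a between-subject factor (group) and a within-subject
#' factor (microstate class), computed from sums of squares: the group effect
#' is tested against subjects-within-groups, class and group x class against
#' the class x subject-within-group residual. Post hoc Welch two-sample
#' contrasts compare the groups per class, Bonferroni-adjusted over the K
#' classes. No sphericity correction is applied.
#'
#' @param parameters data frame with one row per subject x class
#'   (`subject_id`, `group`, `class` columns), e.g. from [backfit_cohort()].
#' @param metric name of the response column, one of `"gev"`,
#'   `"mean_duration_ms"`, `"time_coverage_pct"`, `"occurrence_per_min"`
#'   (any numeric column works).
#' @return object of class `anova_result`: `effects` table (F, df, p) and
#'   `posthoc` table (per-class t, raw and Bonferroni-adjusted p).
#' @export
rm_anova_posthoc <- function(parameters, metric = "time_coverage_pct") {
  if (!metric %in% names(parameters))
    ms_stop(sprintf("metric '%s' not found in the parameter table", metric))
  d <- parameters
  d$y <- d[[metric]]
  d$subject_id <- factor(d$subject_id)
  d$group <- factor(d$group)
  d$class <- factor(d$class)
  tab <- table(d$subject_id, d$class)
  if (any(tab != 1L))
    ms_stop("every subject needs exactly one row per class",
            class = "microstatr_structure_error")
  n_s <- nlevels(d$subject_id); K <- nlevels(d$class); G <- nlevels(d$group)
  grand <- mean(d$y)

  subj_mean <- tapply(d$y, d$subject_id, mean)
  subj_group <- tapply(as.character(d$group), d$subject_id, `[`, 1L)
  group_mean <- tapply(d$y, d$group, mean)
  class_mean <- tapply(d$y, d$class, mean)
  cell_mean <- tapply(d$y, list(d$group, d$class), mean)
  n_per_group <- table(factor(subj_group, levels = levels(d$group)))

  ss_group <- K * sum(n_per_group * (group_mean - grand)^2)
  ss_subj_within <- K * sum((subj_mean - group_mean[subj_group])^2)
  ss_class <- n_s * sum((class_mean - grand)^2)
  ss_interaction <- 0
  for (g in levels(d$group)) for (cl in levels(d$class)) {
    ss_interaction <- ss_interaction + n_per_group[[g]] *
      (cell_mean[g, cl] - group_mean[[g]] - class_mean[[cl]] + grand)^2
  }
  ss_total <- sum((d$y - grand)^2)
  ss_error <- ss_total - ss_group - ss_subj_within - ss_class - ss_interaction

  df_group <- G - 1; df_subj <- n_s - G
  df_class <- K - 1; df_inter <- (G - 1) * (K - 1)
  df_error <- (n_s - G) * (K - 1)
  ms <- function(ss, df) ss / df
  F_group <- ms(ss_group, df_group) / ms(ss_subj_within, df_subj)
  F_class <- ms(ss_class, df_class) / ms(ss_error, df_error)
  F_inter <- ms(ss_interaction, df_inter) / ms(ss_error, df_error)
  effects <- data.frame(
    effect = c("group", "class", "group:class"),
    df1 = c(df_group, df_class, df_inter),
    df2 = c(df_subj, df_error, df_error),
    ss = c(ss_group, ss_class, ss_interaction),
    F = c(F_group, F_class, F_inter),
    p = stats::pf(c(F_group, F_class, F_inter),
                  c(df_group, df_class, df_inter),
                  c(df_subj, df_error, df_error), lower.tail = FALSE),
    stringsAsFactors = FALSE)

  gl <- levels(d$group)
  posthoc <- do.call(rbind, lapply(levels(d$class), function(cl) {
    y1 <- d$y[d$class == cl & d$group == gl[1]]
    y2 <- d$y[d$class == cl & d$group == gl[2]]
    tt <- tryCatch(stats::t.test(y1, y2), error = function(e) NULL)
    data.frame(class = cl,
               mean_1 = mean(y1), mean_2 = mean(y2),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_raw = if (is.null(tt)) 1 else tt$p.value,
               stringsAsFactors = FALSE)
  }))
  names(posthoc)[2:3] <- paste0("mean_", gl)
  posthoc$p_adj <- pmin(1, posthoc$p_raw * K)
  structure(list(metric = metric, effects = effects, posthoc = posthoc,
                 group_levels = gl),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures two-way ANOVA on %s\n", x$metric))
  print(transform(x$effects, F = round(F, 3), p = signif(p, 3)),
        row.names = FALSE)
  cat("Post hoc group contrasts (Bonferroni over classes):\n")
  print(transform(x$posthoc, t = round(t, 3), p_raw = signif(p_raw, 3),
                  p_adj = signif(p_adj, 3)), row.names = FALSE)
  invisible(x)
}

#' Pearson correlations between microstate parameters and covariates
#'
#' @param parameters subject x class parameter table (from
#'   [backfit_cohort()]).
#' @param covariates covariate data frame keyed by `subject_id`.
#' @param pairs data frame with columns `metric`, `class`, `covariate`
#'   naming the requested correlations.
#' @return data frame with `r`, `n`, `p` (two-sided t-test) per pair.
#' @export
pearson_correlations <- function(parameters, covariates, pairs) {
  out <- pairs
  out$r <- NA_real_; out$n <- NA_integer_; out$p <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    sub <- parameters[parameters$class == pairs$class[i], ]
    merged <- merge(sub, covariates, by = "subject_id")
    x <- merged[[pairs$metric[i]]]
    y <- merged[[pairs$covariate[i]]]
    keep <- stats::complete.cases(x, y)
    if (sum(keep) < 3L) ms_stop("fewer than 3 complete pairs")
    ct <- stats::cor.test(x[keep], y[keep])
    out$r[i] <- unname(ct$estimate)
    out$n[i] <- sum(keep)
    out$p[i] <- ct$p.value
  }
  out
}

#' Stepwise multiple linear regression with VIF diagnostics
#'
#' Classical SPSS-style stepwise selection: at each step the candidate with
#' the smallest coefficient p-value enters if `p < p_enter`; any included
#' predictor whose p-value rises above `p_remove` is dropped; iterate to a
#' fixed point. Reports coefficients, R-squared, the entry/removal record and
#' the variance inflation factor of every selected predictor
#' (`VIF_j = 1 / (1 - R2_j)` from regressing predictor j on the others;
#' exactly 1 when a single predictor is selected).
#'
#' @param y numeric response vector.
#' @param candidates data frame of candidate predictors (numeric columns).
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return object of class `stepwise_result`: `selected`, `coefficients`,
#'   `r_squared`, `steps`, `vif`, and the final `lm` fit (or `NULL` for the
#'   empty model).
#' @export
stepwise_regression <- function(y, candidates, p_enter = 0.05, p_remove = 0.1) {
  candidates <- as.data.frame(candidates)
  keep <- stats::complete.cases(y, candidates)
  y <- y[keep]; candidates <- candidates[keep, , drop = FALSE]
  if (length(y) <= ncol(candidates) + 2L)
    ms_stop("need n > #candidates + 2 observations")
  # drop perfectly collinear candidates up front
  qrX <- qr(cbind(1, as.matrix(candidates)))
  if (qrX$rank < ncol(candidates) + 1L) {
    drop_idx <- qrX$pivot[-seq_len(qrX$rank)] - 1L
    drop_idx <- drop_idx[drop_idx > 0]
    message("dropping perfectly collinear candidate(s): ",
            paste(names(candidates)[drop_idx], collapse = ", "))
    candidates <- candidates[, -drop_idx, drop = FALSE]
  }
  selected <- character(0)
  steps <- list()
  coef_p <- function(vars) {
    if (length(vars) == 0L) return(NULL)
    fit <- stats::lm(y ~ ., data = candidates[, vars, drop = FALSE])
    summ <- stats::summary.lm(fit)$coefficients
    list(fit = fit, p = summ[-1L, 4L])
  }
  repeat {
    changed <- FALSE
    # backward removal
    cur <- coef_p(selected)
    if (!is.null(cur)) {
      worst <- which.max(cur$p)
      if (cur$p[worst] > p_remove) {
        steps[[length(steps) + 1L]] <- list(action = "remove",
                                            variable = selected[worst],
                                            p = unname(cur$p[worst]))
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    # forward entry
    pool <- setdiff(names(candidates), selected)
    if (length(pool)) {
      entry_p <- vapply(pool, function(v) {
        f <- coef_p(c(selected, v))
        unname(f$p[length(f$p)])
      }, numeric(1))
      best <- which.min(entry_p)
      if (entry_p[best] < p_enter) {
        steps[[length(steps) + 1L]] <- list(action = "enter",
                                            variable = pool[best],
                                            p = unname(entry_p[best]))
        selected <- c(selected, pool[best])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0L) {
    return(structure(list(selected = character(0), coefficients = numeric(0),
                          r_squared = 0, steps = steps, vif = numeric(0),
                          fit = NULL),
                     class = "stepwise_result"))
  }
  fit <- stats::lm(y ~ ., data = candidates[, selected, drop = FALSE])
  r2 <- stats::summary.lm(fit)$r.squared
  vif <- vapply(selected, function(v) {
    if (length(selected) == 1L) return(1)
    r2j <- stats::summary.lm(
      stats::lm(stats::reformulate(setdiff(selected, v), v),
                data = candidates[, selected, drop = FALSE]))$r.squared
    1 / (1 - min(r2j, 1 - 1e-12))
  }, numeric(1))
  if (any(vif > 10))
    warning("selected predictors are strongly collinear (VIF > 10)")
  structure(list(selected = selected, coefficients = stats::coef(fit),
                 r_squared = r2, steps = steps, vif = vif, fit = fit),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("Stepwise regression: no predictor met the entry criterion\n")
    return(invisible(x))
  }
  cat(sprintf("Stepwise regression: %s selected, R^2 = %.3f\n",
              paste(x$selected, collapse = " + "), x$r_squared))
  print(data.frame(coefficient = x$coefficients,
                   vif = c(NA, x$vif)[seq_along(x$coefficients)]))
  invisible(x)
}
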