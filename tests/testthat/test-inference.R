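test_that("global dissimilarity has the right extremes and algebraic identity", {
  u <- c(2, -1, 0, -1)
  expect_equal(dissimilarity(u, u), 0, tolerance = 1e-12)
  expect_equal(dissimilarity(u, 3 * u), 0, tolerance = 1e-12)
  expect_equal(dissimilarity(u, -u), 2, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    r <- spatial_correlation(a, b, polarity_invariant = FALSE)
    expect_equal(dissimilarity(a, b)^2, 2 * (1 - r), tolerance = 1e-9)
  }
  expect_error(dissimilarity(u, rep(1, 4)), "zero-GFP")
})

test_that("TANOVA degenerates correctly and reaches its separation floor", {
  set.seed(9)
  A <- matrix(rnorm(5 * 16), 5)
  tv <- tanova(A, A, n_permutations = 200, seed = 1)
  expect_equal(tv$observed_diss, 0, tolerance = 1e-12)
  expect_equal(tv$p_value, 1)

  # orthogonal templates, almost no noise: p at the add-one minimum
  t1 <- c(rep(1, 8), rep(-1, 8)); t2 <- rep(c(1, -1), 8)
  A <- matrix(rep(t1, 6), 6, byrow = TRUE) + matrix(rnorm(96, sd = 1e-3), 6)
  B <- matrix(rep(t2, 6), 6, byrow = TRUE) + matrix(rnorm(96, sd = 1e-3), 6)
  tv2 <- tanova(A, B, n_permutations = 999, seed = 2)
  expect_lte(tv2$p_value, 2 / 1000)

  # relabelling the groups leaves the test unchanged (equal sizes)
  tv_ab <- tanova(A, B, n_permutations = 500, seed = 3)
  tv_ba <- tanova(B, A, n_permutations = 500, seed = 3)
  expect_equal(tv_ab$observed_diss, tv_ba$observed_diss, tolerance = 1e-12)
  expect_equal(tv_ab$p_value, tv_ba$p_value)
  expect_error(tanova(A[1, , drop = FALSE], B), ">= 2 subjects")
})

test_that("null TANOVA p-values are calibrated", {
  tpl <- fix_templates(16, 1, seed = 61)
  ps <- vapply(1:120, function(i) {
    set.seed(1000 + i)
    maps <- matrix(rep(tpl$maps, 12), 12, byrow = TRUE) +
      matrix(rnorm(12 * 16), 12)
    tanova(maps[1:6, ], maps[7:12, ], n_permutations = 300,
           seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps <= 0.05), 0.005)
  expect_lt(mean(ps <= 0.05), 0.12)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("mixed-design ANOVA matches the aov() error-stratum oracle", {
  set.seed(13)
  for (rep_i in 1:3) {
    d <- expand.grid(subject_id = sprintf("s%02d", 1:12),
                     class = c("A", "B", "C"), stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 7,
                      "patient", "control")
    d$y <- rnorm(nrow(d)) + (d$group == "patient") * 0.5 +
      (d$class == "B") * 1 + (d$group == "patient") * (d$class == "C") * 0.8
    names(d)[names(d) == "y"] <- "time_coverage_pct"
    res <- rm_anova_posthoc(d, "time_coverage_pct")

    oracle <- summary(aov(time_coverage_pct ~ group * class +
                            Error(factor(subject_id)),
                          data = d))
    f_between <- oracle[["Error: factor(subject_id)"]][[1]]
    f_within <- oracle[["Error: Within"]][[1]]
    expect_equal(res$effects$F[res$effects$effect == "group"],
                 f_between["group", "F value"], tolerance = 1e-9)
    expect_equal(res$effects$F[res$effects$effect == "class"],
                 f_within["class", "F value"], tolerance = 1e-9)
    expect_equal(res$effects$F[res$effects$effect == "group:class"],
                 f_within["group:class", "F value"], tolerance = 1e-9)
  }
})

test_that("ANOVA on a hand-computed toy table reproduces exact sums of squares", {
  # 2 groups x 3 classes, 2 subjects per group; all SS computed by hand
  d <- data.frame(
    subject_id = rep(c("s1", "s2", "s3", "s4"), each = 3),
    group = rep(c("g1", "g1", "g2", "g2"), each = 3),
    class = rep(c("A", "B", "C"), 4),
    y = c(1, 2, 3,   3, 4, 5,   2, 4, 6,   4, 6, 8))
  # grand mean 4; group means 3 and 5 -> SS_group = 3*2*(1)*2 = 12
  # subject means 2,4,4,6 -> SS_subj(within) = 3*((2-3)^2+(4-3)^2+(4-5)^2+(6-5)^2) = 12
  # class means: A=(1+3+2+4)/4=2.5, B=4, C=5.5 -> SS_class = 4*((1.5)^2+0+(1.5)^2) = 18
  res <- rm_anova_posthoc(d, "y")
  expect_equal(res$effects$ss[res$effects$effect == "group"], 12)
  expect_equal(res$effects$ss[res$effects$effect == "class"], 18)
  expect_equal(res$effects$F[res$effects$effect == "group"], 12 / (12 / 2))

  # identical groups: F(group) ~ 0
  d2 <- d
  d2$y <- rep(c(1, 2, 3), 4)
  res2 <- rm_anova_posthoc(d2, "y")
  expect_equal(res2$effects$ss[res2$effects$effect == "group"], 0)
  expect_true(all(res2$posthoc$p_adj == 1))
})

test_that("ANOVA validates the subject x class design", {
  d <- data.frame(subject_id = c("s1", "s1", "s2"), group = "g1",
                  class = c("A", "B", "A"), y = 1:3)
  expect_error(rm_anova_posthoc(d, "y"), "one row per class")
})

test_that("Pearson correlations match closed forms and a hand-computed table", {
  params <- data.frame(subject_id = sprintf("s%d", 1:5), group = "patient",
                       class = "A", gev = c(1, 2, 3, 4, 5) / 10)
  cov_tab <- data.frame(subject_id = sprintf("s%d", 1:5), group = "patient",
                        SDMT = c(2, 4, 6, 8, 10),
                        EDSS = c(1, -2, 0, 2, -1))
  pairs <- data.frame(metric = "gev", class = "A",
                      covariate = c("SDMT", "EDSS"))
  out <- pearson_correlations(params, cov_tab, pairs)
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_equal(out$r[2], 0, tolerance = 1e-12)

  # 5-point hand check: r = cov/(sd_x sd_y)
  x <- c(1, 3, 4, 6, 8); y <- c(2, 3, 7, 8, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  params2 <- data.frame(subject_id = sprintf("s%d", 1:5), group = "p",
                        class = "A", gev = x)
  cov2 <- data.frame(subject_id = sprintf("s%d", 1:5), group = "p", SDMT = y)
  out2 <- pearson_correlations(params2, cov2,
                               data.frame(metric = "gev", class = "A",
                                          covariate = "SDMT"))
  expect_equal(out2$r, r_hand, tolerance = 1e-12)
})

test_that("stepwise regression honours entry/removal thresholds and reports VIF", {
  set.seed(17)
  x <- rnorm(60)
  cand <- data.frame(x = x, n1 = rnorm(60), n2 = rnorm(60), n3 = rnorm(60))
  sw <- suppressWarnings(stepwise_regression(2 * x, cand))  # exact linear fit
  expect_identical(sw$selected, "x")
  expect_equal(sw$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(sw$vif), 1)

  # fixed point: nothing removable above p_remove, nothing enterable below p_enter
  y <- 2 * x + rnorm(60)
  sw2 <- stepwise_regression(y, cand)
  fit <- lm(y ~ ., data = cand[, sw2$selected, drop = FALSE])
  p_in <- summary(fit)$coefficients[-1, 4]
  expect_true(all(p_in <= 0.1))
  for (v in setdiff(names(cand), sw2$selected)) {
    f2 <- lm(y ~ ., data = cand[, c(sw2$selected, v), drop = FALSE])
    expect_gte(summary(f2)$coefficients[v, 4], 0.05)
  }

  # perfectly collinear candidate dropped with a message
  cand3 <- cbind(cand, dup = cand$x * 2)
  expect_message(sw3 <- stepwise_regression(y, cand3), "collinear")
  expect_false("dup" %in% sw3$selected)
})

test_that("all-noise stepwise selects the empty model at the binomial rate", {
  set.seed(23)
  empty <- vapply(1:100, function(i) {
    y <- rnorm(50)
    cand <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50),
                       d = rnorm(50))
    length(stepwise_regression(y, cand)$selected) == 0L
  }, logical(1))
  # P(no candidate enters) ~ (1 - 0.05)^4 ~ 0.81; allow a binomial band
  expect_gt(mean(empty), 0.70)
  expect_lt(mean(empty), 0.93)
})
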