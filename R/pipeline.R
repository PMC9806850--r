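# End-to-end orchestration: simulate -> preprocess -> segment (individual ->
# group -> population) -> backfit -> stats, with per-stage outputs on disk, a
# reproducibility manifest, and resume-from-existing-outputs semantics.

#' Default pipeline configuration
#'
#' Returns the fully-defaulted configuration list for [run_pipeline()]; any
#' entry may be overridden via a YAML config file or the `config` argument.
#' The demo scale (8 + 8 subjects, 64 channels, 60 s at 125 Hz, individual
#' K = 5, population K = 6) exercises the complete two-group analysis in a
#' few minutes on one core.
#'
#' @return named list of settings.
#' @export
pipeline_defaults <- function() {
  list(
    n_patients = 8, n_controls = 8,
    n_channels = 64, sfreq = 125, duration_s = 60,
    snr = 2.0, mean_dwell_ms = 100,
    individual_k = 5, group_k = 5, population_k = 6,
    n_restarts = 10, min_duration_ms = 0,
    n_permutations = 1000,
    metrics = c("gev", "mean_duration_ms", "time_coverage_pct",
                "occurrence_per_min"),
    format = "delimited",
    seed = 1L)
}

read_pipeline_config <- function(config) {
  cfg <- pipeline_defaults()
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (k in names(config)) cfg[[k]] <- config[[k]]
  cfg
}

stage_done <- function(files) length(files) > 0 && all(file.exists(files))

#' Run the full microstate analysis pipeline
#'
#' Executes, in order: cohort simulation, preprocessing (band-pass + average
#' reference), individual segmentation, per-group and whole-population
#' clustering, back-fitting of the population templates, and the group
#' statistics (per-class TANOVA, repeated-measures ANOVA per metric, Pearson
#' correlations, stepwise regression of SDMT). Every stage writes its outputs
#' under `out_dir`; with `resume = TRUE` stages whose outputs already exist
#' are skipped and their files reused. A manifest with the configuration,
#' seeds, package version and per-file MD5 hashes is written at the end.
#'
#' @param config YAML file path or named list overriding
#'   [pipeline_defaults()].
#' @param out_dir output directory (created if needed).
#' @param seed top-level seed; every stage derives its own stream from it.
#' @param resume reuse existing stage outputs instead of recomputing.
#' @return invisibly, a list with the population fit, parameter table,
#'   statistics and the manifest path.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("msrun"),
                         seed = NULL, resume = TRUE) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("recordings", "preprocessed", "templates", "labels", "stats"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  log_line <- function(...) message(sprintf("[pipeline] %s", sprintf(...)))
  ids <- sprintf("S%03d", seq_len(cfg$n_patients + cfg$n_controls))
  ext <- if (cfg$format == "edf") "edf" else "tsv"

  # --- simulate ------------------------------------------------------------
  rec_files <- file.path(out_dir, "recordings", paste0(ids, ".", ext))
  cov_file <- file.path(out_dir, "covariates.csv")
  gt_file <- file.path(out_dir, "ground_truth_parameters.tsv")
  gt_tpl_file <- file.path(out_dir, "ground_truth_templates.tsv")
  if (!(resume && stage_done(c(rec_files, cov_file)))) {
    log_line("simulate: %d subjects, %d channels, %.0f s", length(ids),
             cfg$n_channels, cfg$duration_s)
    scfg <- synthetic_config(n_channels = cfg$n_channels, sfreq = cfg$sfreq,
                             duration_s = cfg$duration_s, snr = cfg$snr,
                             mean_dwell_ms = cfg$mean_dwell_ms)
    cohort <- simulate_cohort(scfg, cfg$n_patients, cfg$n_controls,
                              seed = derive_seed(cfg$seed, "simulate"))
    for (i in seq_along(cohort$recordings))
      write_recording(cohort$recordings[[i]], rec_files[i])
    write_covariates(cohort$covariates, cov_file)
    write_parameters(cohort$ground_truth$realized, gt_file)
    write_templates(cohort$ground_truth$templates, gt_tpl_file)
  } else log_line("simulate: reusing existing outputs")

  # --- preprocess ----------------------------------------------------------
  pre_files <- file.path(out_dir, "preprocessed", paste0(ids, ".tsv"))
  if (!(resume && stage_done(pre_files))) {
    for (i in seq_along(ids)) {
      rec <- read_recording(rec_files[i])
      rec <- suppressMessages(preprocess(rec, band = c(1, 40),
                                         target_sfreq = cfg$sfreq))
      write_recording(rec, pre_files[i])
    }
    log_line("preprocess: filtered and re-referenced %d recordings", length(ids))
  } else log_line("preprocess: reusing existing outputs")

  # --- segment -------------------------------------------------------------
  ind_files <- file.path(out_dir, "templates", paste0(ids, "_individual.tsv"))
  grp_files <- file.path(out_dir, "templates",
                         c("group_patient.tsv", "group_control.tsv"))
  pop_file <- file.path(out_dir, "templates", "population.tsv")
  recs <- NULL
  if (!(resume && stage_done(c(ind_files, grp_files, pop_file)))) {
    recs <- lapply(pre_files, read_recording)
    ind_sets <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      fit <- microstates(recs[[i]], k = cfg$individual_k,
                         n_restarts = cfg$n_restarts,
                         seed = derive_seed(cfg$seed, paste0("segment", i)))
      ind_sets[[i]] <- fit$templates
      write_templates(fit$templates, ind_files[i])
    }
    groups <- vapply(recs, function(r) r$group, "")
    for (g in c("patient", "control")) {
      gfit <- group_segmentation(ind_sets[groups == g], k = cfg$group_k,
                                 level = "group",
                                 n_restarts = cfg$n_restarts,
                                 seed = derive_seed(cfg$seed, paste0("grp", g)))
      write_templates(gfit$templates,
                      grp_files[if (g == "patient") 1 else 2])
    }
    pop <- group_segmentation(ind_sets, k = cfg$population_k,
                              level = "population",
                              n_restarts = cfg$n_restarts,
                              seed = derive_seed(cfg$seed, "population"))
    montage <- recs[[1]]$montage
    pop_templates <- if (!is.null(montage))
      label_microstates(pop$templates, montage) else pop$templates
    write_templates(pop_templates, pop_file)
    log_line("segment: population K = %d, pooled GEV = %.3f",
             nrow(pop_templates$maps), pop$gev_total)
  } else log_line("segment: reusing existing outputs")

  # --- backfit -------------------------------------------------------------
  par_file <- file.path(out_dir, "parameters.tsv")
  lab_files <- file.path(out_dir, "labels", paste0(ids, ".tsv"))
  pop_templates <- read_templates(pop_file)
  if (!(resume && stage_done(c(par_file, lab_files)))) {
    if (is.null(recs)) recs <- lapply(pre_files, read_recording)
    params <- backfit_cohort(recs, pop_templates,
                             min_duration_ms = cfg$min_duration_ms)
    write_parameters(params, par_file)
    for (i in seq_along(ids)) {
      series <- assign_labels(recs[[i]], pop_templates)
      write_labels(series, lab_files[i])
    }
    log_line("backfit: %d parameter rows", nrow(params))
  } else log_line("backfit: reusing existing outputs")

  # --- stats ---------------------------------------------------------------
  stat_files <- file.path(out_dir, "stats",
                          c("tanova.tsv", "regression.tsv",
                            paste0("anova_", cfg$metrics, ".tsv")))
  params <- read_parameters(par_file)
  covariates <- read_covariates(cov_file)
  if (!(resume && stage_done(stat_files))) {
    if (is.null(recs)) recs <- lapply(pre_files, read_recording)
    groups <- vapply(recs, function(r) r$group, "")
    tanova_rows <- lapply(seq_along(pop_templates$class_labels), function(k) {
      maps <- t(vapply(seq_along(recs), function(i) {
        subject_class_map(recs[[i]], read_labels(lab_files[i]), k,
                          pop_templates)
      }, numeric(cfg$n_channels)))
      keep <- rowSums(is.na(maps)) == 0
      if (sum(keep & groups == "patient") < 2 ||
          sum(keep & groups == "control") < 2) {
        return(data.frame(class = pop_templates$class_labels[k],
                          observed_diss = NA, p_value = NA))
      }
      tv <- tanova(maps[keep & groups == "patient", , drop = FALSE],
                   maps[keep & groups == "control", , drop = FALSE],
                   n_permutations = cfg$n_permutations,
                   seed = derive_seed(cfg$seed, paste0("tanova", k)))
      data.frame(class = pop_templates$class_labels[k],
                 observed_diss = tv$observed_diss, p_value = tv$p_value)
    })
    utils::write.table(do.call(rbind, tanova_rows), stat_files[1],
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (m in cfg$metrics) {
      av <- rm_anova_posthoc(params, m)
      utils::write.table(cbind(metric = m, av$effects),
                         file.path(out_dir, "stats", paste0("anova_", m, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(av$posthoc,
                         file.path(out_dir, "stats", paste0("posthoc_", m, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    pat <- covariates[covariates$group == "patient", ]
    gevA <- params[params$class == "A", c("subject_id", "gev")]
    dpat <- merge(pat, gevA, by = "subject_id")
    sw <- tryCatch(
      stepwise_regression(dpat$SDMT,
                          dpat[, c("gev", "disease_duration", "EDSS", "ARR")]),
      error = function(e) {
        log_line("stats: stepwise regression skipped (%s)", conditionMessage(e))
        list(selected = character(0))
      })
    sw_tab <- if (length(sw$selected)) {
      data.frame(term = names(sw$coefficients), coefficient = sw$coefficients,
                 r_squared = sw$r_squared,
                 vif = c(NA, sw$vif), row.names = NULL)
    } else data.frame(term = character(0), coefficient = numeric(0),
                      r_squared = numeric(0), vif = numeric(0))
    utils::write.table(sw_tab, stat_files[2], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    log_line("stats: TANOVA + ANOVA + regression written")
  } else log_line("stats: reusing existing outputs")

  # --- manifest ------------------------------------------------------------
  all_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  all_files <- setdiff(all_files, file.path(out_dir, c("manifest.yaml", "report.md")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("microstatr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "metrics")],
    metrics = as.list(cfg$metrics),
    hashes = as.list(tools::md5sum(sort(all_files))))
  names(manifest$hashes) <- sub(paste0("^", out_dir, "/?"), "",
                                names(manifest$hashes))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(out_dir = out_dir, parameters = params,
                 templates = pop_templates,
                 manifest = file.path(out_dir, "manifest.yaml")))
}

# Polarity-aligned mean map of the samples a subject spends in class k
# (each sample's sign aligned to the template before averaging), NA map if
# the class never occurs.
subject_class_map <- function(rec, series, k, templates) {
  idx <- which(series$labels == k)
  if (length(idx) < 2L) return(rep(NA_real_, nrow(rec$data)))
  X <- rec$data[, idx, drop = FALSE]
  X <- X - rep(colMeans(X), each = nrow(X))
  sgn <- sign(drop(templates$maps[k, ] %*% X))
  sgn[sgn == 0] <- 1
  rowMeans(X * rep(sgn, each = nrow(X)))
}

#' Summarise a completed pipeline run
#'
#' Reads the outputs under `run_dir` and renders a markdown report: the
#' chosen templates and their match to the per-group sets, per-class group
#' means of every temporal parameter, TANOVA p-values and the regression
#' table. Idempotent; rerunning overwrites `report.md` with identical
#' content for an unchanged run directory.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return the report text, invisibly; also written to
#'   `file.path(run_dir, "report.md")`.
#' @export
microstate_report <- function(run_dir) {
  par_file <- file.path(run_dir, "parameters.tsv")
  if (!file.exists(par_file))
    ms_stop(sprintf("no completed run in '%s' (parameters.tsv missing)", run_dir))
  params <- read_parameters(par_file)
  pop <- read_templates(file.path(run_dir, "templates", "population.tsv"))
  lines <- c("# Microstate pipeline report", "",
             sprintf("Population template set: %d classes (%s)",
                     length(pop$class_labels),
                     paste(pop$class_labels, collapse = ", ")), "")
  for (g in c("group_patient.tsv", "group_control.tsv")) {
    gf <- file.path(run_dir, "templates", g)
    if (file.exists(gf)) {
      m <- match_templates(pop, read_templates(gf))
      lines <- c(lines, sprintf("Template match, population vs %s:",
                                sub("\\.tsv$", "", g)),
                 sprintf("  %s -> %s: |r| = %.2f", m$label1, m$label2,
                         m$abs_correlation), "")
    }
  }
  num_cols <- c("gev", "mean_duration_ms", "time_coverage_pct",
                "occurrence_per_min")
  lines <- c(lines, "Per-class group means (mean +/- SD):", "")
  for (m in num_cols) {
    lines <- c(lines, sprintf("## %s", m))
    agg_m <- stats::aggregate(params[[m]],
                              by = list(class = params$class, group = params$group),
                              FUN = mean)
    agg_s <- stats::aggregate(params[[m]],
                              by = list(class = params$class, group = params$group),
                              FUN = stats::sd)
    for (i in seq_len(nrow(agg_m)))
      lines <- c(lines, sprintf("  %s / %s: %.3f +/- %.3f", agg_m$class[i],
                                agg_m$group[i], agg_m$x[i], agg_s$x[i]))
    lines <- c(lines, "")
  }
  tv_file <- file.path(run_dir, "stats", "tanova.tsv")
  if (file.exists(tv_file)) {
    tv <- utils::read.table(tv_file, header = TRUE, sep = "\t")
    lines <- c(lines, "TANOVA per class (patients vs controls):",
               sprintf("  %s: DISS = %.3f, p = %.4g", tv$class,
                       tv$observed_diss, tv$p_value), "")
  }
  rg_file <- file.path(run_dir, "stats", "regression.tsv")
  if (file.exists(rg_file)) {
    rg <- utils::read.table(rg_file, header = TRUE, sep = "\t")
    lines <- c(lines, "Stepwise regression (SDMT ~ class-A GEV + clinical):")
    lines <- if (nrow(rg)) c(lines, utils::capture.output(print(rg))) else
      c(lines, "  empty model")
  }
  txt <- paste(lines, collapse = "\n")
  writeLines(txt, file.path(run_dir, "report.md"))
  invisible(txt)
}
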