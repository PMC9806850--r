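# microstatr

Resting-state EEG **microstate** analysis in R: segmentation of scalp
topographies into quasi-stable template maps, back-fitting of those templates
onto continuous recordings to quantify their temporal dynamics, and
group-level statistics — aimed at electrophysiologists studying large-scale
network dynamics in clinical cohorts (e.g. relapsing–remitting multiple
sclerosis versus healthy controls) and at methodologists who need a fully
synthetic, ground-truthed benchmark for microstate estimators.

## The method

Broad-band EEG is read as a sequence of voltage topographies that remain
quasi-stable for ~80–120 ms. The pipeline:

1. **GFP peaks.** Global field power,
   `GFP(t) = sqrt(mean_i (v_i(t) − v̄(t))²)`, is the spatial SD across
   channels; maps at its local maxima have the best signal-to-noise and are
   the clustering input.
2. **Polarity-invariant modified k-means.** Maps are assigned to the
   template with maximal squared spatial correlation `r²`; templates are
   updated as the dominant eigenvector of the GFP²-weighted scatter of their
   maps (so a map and its sign-flip are one state). Fit quality is the
   global explained variance
   `GEV = Σ_p GFP_p² r²(x_p, T_a(p)) / Σ_p GFP_p²`.
3. **Meta-criterion.** Seven cluster-validity indices on the distance
   `d = 1 − r²` vote for the number of maps; the lower median wins.
4. **Two-level clustering.** Individual templates → per-group → population
   template set, labelled A–F against canonical archetypes.
5. **Back-fitting.** Every sample is labelled with its best template; per
   class this yields mean duration (ms), time coverage (%), occurrence
   (/min) and GEV, with the identities `Σ TC = 100` and
   `TC = occ × MD / 600`.
6. **Group statistics.** TANOVA (permutation test on the global
   dissimilarity of GFP-normalised group-mean maps), mixed-design
   repeated-measures ANOVA with Bonferroni post hoc contrasts, Pearson
   correlations, and stepwise regression (entry p < .05 / removal p > .10)
   with VIF diagnostics.

A semi-Markov synthetic cohort generator (gamma dwell times, rectified
10 Hz GFP envelope, spatially correlated sensor noise, two groups with
different template repertoires, covariates coupled to the generative
dynamics) provides ground truth for every stage; I/O covers EDF and a plain
tab-separated dialect.

## Worked example

```r
library(microstatr)

cfg  <- synthetic_config(n_channels = 32, duration_s = 20)
mont <- build_spherical_montage(32)
tpl  <- make_templates(mont, 4, seed = 7)
seq4 <- simulate_state_sequence(4, 2500, 125, seed = 7)
rec  <- synthesize_recording(tpl, seq4$states, mont, cfg, seed = 7)

fit <- microstates(rec, k = 4, n_restarts = 5, seed = 7)
fit
#> Microstate segmentation (individual)
#>   K = 4 maps, 651 GFP-peak topographies, GEV = 0.802

match_templates(fit$templates, tpl)
#>    index1 index2 label1 label2 abs_correlation
#> M1      1      1     M1      A       0.9970245
#> M2      2      3     M2      C       0.9969340
#> M3      3      4     M3      D       0.9990154
#> M4      4      2     M4      B       0.9980145

labels <- predict(fit, min_duration_ms = 30)
compute_parameters(labels, fit$gfp, rec, fit$templates)[, 1:5]
```

The fit explains ~80 % of GFP-weighted topographic variance at SNR 2, each
recovered template matches its generative map at |r| > 0.996, and the
parameter table gives each class's duration/coverage/occurrence/GEV. The
full cohort analysis is one call:

```r
run <- run_pipeline(list(n_patients = 8, n_controls = 8, duration_s = 60),
                    out_dir = "msdemo", seed = 1)
cat(microstate_report("msdemo"))
```

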