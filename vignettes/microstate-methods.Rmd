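---
title: "EEG microstate analysis with microstatr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis with microstatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The model

Resting-state EEG can be described as a sequence of quasi-stable scalp
potential topographies — *microstates* — each persisting for roughly
80–120 ms before abruptly giving way to the next. `microstatr` implements the
standard analysis built on that description:

1. **Segmentation.** The global field power
   $\mathrm{GFP}(t) = \sqrt{\tfrac1N \sum_i (v_i(t) - \bar v(t))^2}$
   (the spatial standard deviation across the $N$ channels) indexes the
   momentary strength of the topography; its local maxima are the moments of
   best topographic signal-to-noise. The maps at GFP peaks are clustered with
   a *polarity-invariant modified k-means*: similarity between a map $x$ and a
   template $T_k$ is the squared spatial correlation $r^2(x, T_k)$, so a map
   and its sign-flipped copy belong to the same class — the convention for
   spontaneous EEG, where generator polarity alternates. The quality of a
   segmentation is its *global explained variance*
   $$\mathrm{GEV} = \frac{\sum_p \mathrm{GFP}_p^2\, r^2(x_p, T_{a(p)})}
                         {\sum_p \mathrm{GFP}_p^2},$$
   the GFP²-weighted fraction of topographic variance the templates explain.
2. **Choice of K.** Seven cluster-validity indices (Krzanowski–Lai,
   silhouette, inverted Davies–Bouldin, point-biserial, Dunn,
   Goodman–Kruskal gamma, and a predictive-residual criterion), each adapted
   to the correlation distance $d = 1 - r^2$, vote for an optimal number of
   maps; the meta-choice is the lower median of the votes. The identity of
   this index set is a package design decision: validity "meta-criteria" in
   the microstate literature combine several such measures but the exact
   seven are rarely specified, so ours is a documented stand-in, and a run
   whose votes disagree widely (inter-quartile range above one) is flagged
   as having no stable optimum.
3. **Two-level clustering.** Templates are estimated per subject, then the
   pooled individual templates are re-clustered per group and across the
   whole cohort, yielding the shared population maps used for all
   between-group comparisons.
4. **Back-fitting.** Every sample of the continuous recording — not only GFP
   peaks — is labelled with the template of maximal $|r|$; from the label
   series come the four temporal parameters per class: mean duration (MD,
   ms), time coverage (TC, %), occurrence (appearances per minute) and GEV.
   By construction $\sum_k \mathrm{TC}_k = 100$ and
   $\mathrm{TC}_k = \mathrm{occ}_k \cdot \mathrm{MD}_k / 600$ for every
   class; the test suite asserts both.
5. **Group inference.** Topographies are compared with TANOVA — the global
   dissimilarity $\mathrm{DISS}(u,v) = \mathrm{GFP}(\hat u - \hat v)$ between
   GFP-normalised group-mean maps, referenced to a permutation null over
   subject labels, with the add-one estimator
   $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$.
   Temporal parameters are compared with a mixed-design repeated-measures
   ANOVA (between: group; within: class) computed from sums of squares, with
   per-class Welch contrasts Bonferroni-corrected over the K classes.
   Associations with clinical/cognitive covariates use Pearson correlation
   and SPSS-style stepwise multiple regression (entry p < .05, removal
   p > .10) with variance-inflation factors $1/(1-R_j^2)$.

## The synthetic cohort: what it emulates and what it does not

No public recording accompanies the analysis this package operationalises,
so every claim is validated on a generator with known ground truth
(`synthetic_config()`, `simulate_cohort()`):

* **Semi-Markov state sequence.** Classes alternate according to a
  transition matrix (uniform off-diagonal by default, zero diagonal); dwell
  times are gamma-distributed with shape 4 and mean 100 ms. An explicit
  dwell law is used instead of a first-order Markov chain because observed
  microstate durations sit far above the geometric-dwell regime at 125 Hz;
  shape 4 gives a realistic coefficient of variation of 0.5.
* **Emission model.** `data(t) = s(t) a(t) T_{L(t)} + noise`, with `a(t)` a
  rectified 10 Hz sinusoid smoothed by a 40 ms Hann window — so GFP maxima
  arrive at the realistic ~20/s — and `s(t)` a per-dwell random sign
  (polarity flips, toggleable). Noise is spatially correlated Gaussian
  (squared-exponential in great-circle distance, length 0.6 rad), scaled so
  that signal power / noise power equals the configured SNR (default 2).
* **Two groups.** Controls draw from classes {A, B, C, D, F}, patients from
  {A, B, C, D, E}; dwell means are multiplied per group (patients A×1.3,
  B×1.2; controls D×1.3). These effect directions emulate the qualitative
  group differences the analysis is designed to detect; no quantitative
  effect sizes were available to calibrate against, so they are scenario
  parameters, not estimates.
* **Covariates.** SDMT is linear in the *generative* class-A occupancy with
  noise variance fixed by a target R² of 0.3, and disease duration is
  coupled analogously to class-A mean dwell (target R² 0.1) — coupling to
  the generative rather than the estimated quantities makes estimator bias
  measurable. Remaining covariates (age, EDSS, ARR, CVLT-II, BVMT-R) are
  drawn from plausible clinical distributions and carry no signal.
* **Generation rate.** Recordings are generated directly at the 125 Hz
  analysis rate. The preprocessing chain (1–40 Hz zero-phase Butterworth,
  decimation, spherical-spline interpolation, average reference) is
  validated on purpose-built fixtures (pure sinusoids, low-order harmonic
  fields) rather than by generating cohorts at 1 kHz, which would multiply
  simulation cost eightfold without changing the study conditions.

Not emulated: ocular/cardiac artifacts (the ICA stage is therefore a
pluggable no-op hook), 1/f background spectra beyond the correlated-noise
model, volume-conduction forward physics, and electrode-digitisation error.
Passing recovery tests consequently show the *estimator chain* is correct
and well calibrated — not that real recordings meet its assumptions.

## Numerical choices

* **Template update.** Cluster templates are updated as the dominant
  eigenvector of the GFP²-weighted scatter of the assigned (unit-norm) maps.
  The weighting makes each assign/update cycle an exact coordinate ascent on
  GEV, so GEV is non-decreasing across iterations (asserted at run time);
  with unweighted updates that guarantee would not hold.
* **Initialisation.** Restarts use k-means++-style seeding in the
  correlation distance: templates are drawn with probability proportional to
  $1 - \max r^2$ against those already chosen. This matters for population
  clustering, where a class carried by one group contributes only a small
  fraction of the pooled maps and uniform seeding routinely misses it.
* **Empty clusters** are re-seeded from the worst-explained map.
* **Convergence** is declared when the GEV gain drops below `tol` (1e-7).
* **Ties.** GFP-peak plateaus count their first sample; back-fitting ties go
  to the previous sample's label (temporal continuity), else the lowest
  class index.
* **Degenerate inputs.** Zero-variance samples inherit the previous label
  with correlation 0 and are counted; constant recordings are rejected for
  segmentation ("too few peaks"); interpolating ≥ 20 % of channels is
  refused.
* **Resampling** uses zero-phase decimation (Chebyshev + `filtfilt`) for
  integer factors; polyphase resampling handles non-integer rational ratios.
* **Spherical spline** defaults m = 4, 50 Legendre terms, λ = 1e-5 —
  standard practice for scalp interpolation; the solver refuses
  ill-conditioned systems (rcond < 1e-14) rather than returning garbage.

## Back-fitting and the duration bias

Sample-wise argmax labelling is exact in the noiseless limit, but at SNR 2
a few percent of samples — concentrated where the GFP envelope dips — flip
to a wrong class. Such isolated flips barely move time coverage (the
mislabels largely cancel) yet fragment dwell runs, biasing mean duration
downward by tens of percent. This is the known reason temporal smoothing
exists in microstate practice. The package default is *no* smoothing
(`min_duration_ms = 0`), matching the literal description of the analysis it
re-implements; the recovery experiments in the test suite and acceptance
script back-fit with a 30 ms minimum-duration smoothing, the field's
standard remedy, and under that configuration recover coverage within a
fraction of a percentage point and mean duration within a few percent.
Users comparing against the defaults should expect the duration bias.

Two further statistical facts worth knowing:

* On fully-labelled data, time coverage sums to exactly 100 % per subject,
  so the between-subject (group) main effect of an ANOVA on coverage is
  0/0 — reported as NaN. Group differences in coverage live entirely in the
  group × class interaction and the per-class contrasts.
* Stepwise selection admits pure-noise predictors at roughly the entry
  α-level per candidate: with four noise candidates at p < .05, the true
  predictor is selected *alone* in only about $0.95^4 \approx 81\%$ of
  replicates even when it is always included. That is a property of
  stepwise regression, not of this implementation, and the calibration test
  asserts exactly the binomial rate.

## Problem sizes

The validation suite runs, per scenario: 10–20 seeds of 120 s single-subject
recordings at 64 channels for template/parameter recovery and K-selection;
20 seeds of an 8 + 8-subject, 60 s cohort for the two-group analysis; 200
null replicates for TANOVA calibration; and 100 replicates of the n = 50
regression scenario. These sizes keep every recovery estimate's Monte-Carlo
error well inside the asserted tolerances.

## A worked run

```{r, eval = FALSE}
run <- run_pipeline(list(n_patients = 8, n_controls = 8, duration_s = 60),
                    out_dir = "msdemo", seed = 1)
cat(microstate_report("msdemo"))
```

The report lists the population classes (labelled A–F against analytic
archetype maps), their match to the per-group template sets, per-class group
means of the four temporal parameters, per-class TANOVA p-values and the
stepwise regression table for SDMT.

## Known limitations

* No sphericity correction in the repeated-measures ANOVA (class has K > 2
  levels); p-values for the within-subject effects are anticonservative
  under strong non-sphericity.
* Class labels A–F are assigned by matching against idealised analytic
  archetypes; on real data the canonical labels should be checked visually.
* TANOVA operates on subject mean maps (polarity-aligned per class); a
  per-timepoint variant is out of scope.
* The EDF codec covers continuous 16-bit recordings only (no annotations,
  no discontinuous records).
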