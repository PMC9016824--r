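---
title: "Two-slope amyloid quantification from short dynamic PiB scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-slope amyloid quantification from short dynamic PiB scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Amyloid burden on ^11^C-PiB PET is conventionally quantified late in the
scan: SUVR is the ratio of target to reference-region uptake over a 30–60
min window, and DVR is the slope of the reference-Logan plot over the same
window. Both need the full 60-min acquisition and a reference region
(cerebellar cortex) assumed free of specific binding. `aqindex` implements
a reference-free alternative computable from the first 30 minutes: the
amyloid quantification index (AQI), which exploits the fact that
amyloid-positive tissue shows *greater mid-phase retention* and a *slower
clearance from the peak* than healthy tissue.

## The index

A region's time-activity curve (TAC) `S(t)` is indexed by frame mid-time,
with `S(0)` defined as the first-frame (0–10 s) average. Two slopes are
combined:

$$\mathrm{AQI}_{roi} = a\,\frac{S(t_1) - S(0)}{t_1}
  - (1-a)\,\frac{S(t_{max}) - S(t_2)}{t_2 - t_{max}},$$

normalized by the injected dose (MBq). The first term is the net retention
slope from injection to `t1`; the second is the magnitude of the clearance
slope from the uptake peak (`t_max`, the mid-time of the maximal frame) to
`t2`. Retention raises the first term, slow clearance shrinks the second,
so both pathological features push the index up. With the default
parameters `a = 0.5`, `t1 = t2 = 1650` s the index collapses to a single
evaluation of `S` at 1650 s besides `S(0)` and the peak:

$$\mathrm{AQI}_{roi} = 0.5\,\frac{S(1650) - S(0)}{1650}
  - 0.5\,\frac{S(t_{max}) - S(1650)}{1650 - t_{max}},$$

so no frame ending after 1800 s is needed (`truncate_tac(tac, 1800)`
provably never changes the default index — the last retained mid-time is
1650 s).

Sign conventions matter here: the clearance term must be the *drop from the
peak* (`S(t_max) − S(t_2)` over `t_2 − t_{max}`), subtracted. Written any
other way the index would decrease with amyloid load, contradicting its
rationale; the worked hand example in the test-suite (`S(0)=10`, peak 100
at 150 s, `S(1650)=70` → AQI = 0.00818...) pins this down.

### Tunable parameters

| parameter | unit | default | role |
|---|---|---|---|
| `a` | – | 0.5 | weight between retention and clearance slopes |
| `t1` | s | 1650 | end point of the retention slope |
| `t2` | s | 1650 | end point of the clearance slope; must exceed `t_max` |
| interpolation | – | linear in (mid-time, activity) | `S(t)` between frames |

`tune_aqi_params()` re-derives `(a, t1, t2)` for any cohort by grid search
(defaults: `t1 ∈ [50, 3300]` s and `t2 ∈ [300, 3300]` s in 50-s steps,
`a ∈ [0, 1]` in 0.1 steps), scoring each point by stratified 10-fold
cross-validated logistic classification and breaking accuracy ties by
minimal required scan time `max(t1, t2)`, then minimal `t1`, then minimal
`a`. The `t1` grid starts at 50 s because the index divides by `t1`; a zero
starting point would be undefined. Grid points where some subject's peak
falls at or after `t2` make the clearance slope undefined; they are
excluded from the search (with a message) rather than failing it.
Whether grid-search accuracy should be CV accuracy or training accuracy is
ambiguous in common practice; CV accuracy is used here, with the fold
assignment fixed across grid points so the surface is comparable.

## From regions to a subject-level index

Candidate regions' AQI values form a feature matrix. `lasso_select()` fits
the lasso path of the 0/1 group label (HC = 0, AD = 1) on internally
standardized features with squared-error loss, picks the regularization
strength by the cross-validated one-standard-error rule (the largest λ
whose CV MSE is within one SE of the minimum), and returns the surviving
regions ordered by |β|. Using the label as a quantitative response (rather
than a binomial lasso) matches the MSE-based formulation of the 1-SE rule;
features are standardized before penalization so coefficients are
comparable across regions. "Selected" means |β| above a 1e-6 floor — a
numerical-zero guard, not a significance cutoff.

`aqi_fit()` then z-scores the selected regions' AQI with training-set
means/SDs and regresses the label on the z-scores by OLS, giving the
subject-level index `AQI_overall = b0 + b1 X1 + b2 X2 + ...`. On a
balanced cohort the intercept is exactly 0.5 (the label mean), a useful
sanity anchor. `predict()` applies the *stored training statistics* to new
subjects — never re-standardizing on test data.

## Comparators

- `compute_suvr()`: duration-weighted mean activity ratio over frames whose
  mid-times fall in the closed window [1800, 3600] s. With the standard
  PiB framing these are the six 5-min frames with mids 1950–3450 s, all
  equal duration, so the weighting is a no-op there; it matters for
  irregular schedules.
- `logan_dvr()`: for each window frame, `y = ∫₀^t C_T/C_T(t)` against
  `x = ∫₀^t C_ref/C_T(t)` (trapezoidal integrals of the piecewise-linear
  TACs, anchored at `(0, S(0))`); DVR is the unweighted OLS slope. The
  `1/k2'` correction term is off by default (no population `k2'` is
  assumed); pass `k2_ref_pop` to enable it. Unweighted OLS is a choice —
  weighting schemes exist but none is canonical without voxel noise
  estimates.

## Classification and statistics

`stratified_folds()` balances each group across folds to within one
subject (50 + 50 with k = 10 gives exactly 5 + 5 per fold).
`fit_logistic()` is IRLS with a small L2 ridge (1e-6) on the slope only:
separable data — routine in this regime — would otherwise drive the
maximum-likelihood slope to infinity. Convergence is a relative coefficient
change below 1e-8 within 100 iterations; non-convergence is an error, not
a silent result. `roc_analysis()` computes AUC by the rank (Mann–Whitney)
formulation with ties counted one half, sweeps thresholds over the
distinct scores with the rule "score ≥ threshold ⇒ AD", and reports the
threshold maximizing Youden's J, ties broken toward higher specificity.
"Optimal threshold" is reported on the measure scale by running the same
sweep on the raw measure values — out-of-fold probabilities come from ten
different fold models and are not a single monotone transform of the
measure, so a probability-scale threshold would not be portable to new
data. Held-out evaluation (`threshold_metrics()`) always reuses the
training-derived threshold.

Effect size is Cohen's d with pooled SD, AD minus HC. Group separation is
tested by Kruskal–Wallis (kept for two groups rather than swapping in a
rank-sum test; `stats::kruskal.test` supplies the tie-corrected H, with an
explicit guard returning H = 0, p = 1 when every value is identical and the
tie correction denominator vanishes). Correlations with MMSE and CDR-SOB
are Pearson product-moment with t-distribution p-values, missing scores
dropped pairwise.

## The synthetic cohort

Because the index's discriminative claims can only be checked against
known truth, the package ships a kinetic simulator rather than data files.

- **Plasma input**: a Feng-type tri-exponential bolus,
  `Cp(t) = (A1 u − A2 − A3)e^{−λ1 u} + A2 e^{−λ2 u} + A3 e^{−λ3 u}` after a
  10-s delay. Defaults (`A1 = 3000` Bq/ml/s, `A2 = 500`, `A3 = 200` Bq/ml,
  `λ = 0.035, 0.0025, 0.00015` /s) were fixed once so that the bolus peaks
  within the first half minute, tissue frames peak between 80 and 240 s
  for every plausible kinetic draw, and plasma is non-negative over the
  hour. Amplitudes are nominal for 370 MBq and scale linearly with the
  drawn dose (uniform 6–20 mCi, stored in MBq at 37 MBq/mCi).
- **Reference region**: one-tissue compartment solution
  `C_ref = K1 (Cp ⊗ e^{−k2 t})` with `K1 = 0.3` ml/ml/min,
  `k2 = 0.15` /min, identical distributions in both groups (a 5% gain SD
  models delivery variability) — the "no specific binding in cerebellum"
  assumption made literal.
- **Target regions**: SRTM curves
  `C_T = R1 C_ref + (k2 − R1 k2a)(C_ref ⊗ e^{−k2a t})`,
  `k2a = k2/(1+BPND)`. This generative choice gives *exact* ground truth
  `DVR = 1 + BPND` without arterial-sampling assumptions, so the Logan
  implementation can be validated against truth (noise-free recovery is
  within 5% for BPND ≤ 1.5; the residual bias is the well-known Logan
  underestimation plus frame-averaging, both small here).
- **Binding presets**: HC BPND ≈ N(0.1, 0.05) truncated at 0 everywhere;
  AD draws N(0.9, 0.25) in the caudal anterior cingulate and N(0.4, 0.15)
  in the caudate, with the remaining cortical regions at HC-like levels in
  both groups. Giving the caudate a weaker effect than the cingulate makes
  the region *ranking* informative (the selection stage should find the
  cingulate dominant), and restricting the signal to two regions gives the
  lasso a sparse truth to recover. AD relative delivery is reduced
  (R1 ≈ N(0.85, 0.05) vs N(1.0, 0.05)), reproducing the early-frame flow
  deficit; `k2 = R1 k2_ref` keeps the reference-efflux ratio consistent.
- **Noise**: zero-mean Gaussian per frame with
  `sd = noise_level √(max(S,0)/duration)` (default `noise_level = 5`) —
  count-statistics-like, shorter frames noisier, negative excursions kept
  as real reconstructions produce them. Poisson realism, scanner PSF and
  motion are deliberately out of scope.
- **Clinical scores**: MMSE = 29 − 8·(mean featured BPND) + N(0, 1.2)
  clipped to [0, 30] and rounded; CDR-SOB for AD =
  5·(mean featured BPND) + N(0, 0.8) clipped to [0, 9] in half-point
  steps, 0 for every HC. These produce mild-AD-like ranges (MMSE low 20s,
  CDR-SOB ~2–6) and the expected correlation signs, nothing more.

With these presets the default 50 + 50 cohort separates strongly (CV
accuracy near 1, effect sizes ≈ 4–6): the prescribed group distributions
overlap only in their tails. Passing tests on this cohort therefore shows
the *machinery* is correct — recovery of known DVR, selection of the true
signal regions, threshold transfer — not that any particular accuracy will
be attained on real scans, where biological overlap, partial-volume
effects and reference-region amyloid push all measures down.

## Numerical choices

- Time is seconds everywhere internally; readers/writers do not convert
  (files carry `_s` columns).
- Frame activity is the value at the frame mid-time for interpolation and
  peak finding; the simulator conversely *averages* its 0.5-s fine grid
  over each frame, mirroring scanner frame integration. The spacing
  between the two conventions is part of what the Logan tolerance absorbs.
- Below the first mid-time the TAC is held at `activity[1]`, the only
  choice consistent with `S(0)` being the first-frame average; beyond the
  last mid-time queries are an error, never an extrapolation.
- Convolutions use an exponentially weighted trapezoid recursion on the
  0.5-s grid (`O(n)`, exact for constant inputs); the one-tissue solution
  was validated against an independent ODE integration.
- The 1-s default interpolation step quoted for "fine sampling" elsewhere
  is immaterial here: all index evaluations are closed-form linear
  interpolations, so results are grid-step-free by construction.
- Tie-breaks are everywhere deterministic (earliest peak frame, higher
  specificity threshold, minimal-scan-time grid corner) so that a fixed
  seed reproduces every artifact bit for bit.

## Problem sizes

The bundled tests and the acceptance script run the full study at its
native size — 50 + 50 training and 10 + 10 testing subjects, 6 regions,
26 frames, 0.5-s simulation grid — which completes in seconds; the
grid-search contract is exercised on constructed 10-subject toy cohorts
with small custom grids, since the full default grid (≈ 40 000 points,
each a 10-fold CV) is a batch-scale computation users opt into via
`tune_aqi_params()` or the `optimize --coarse` CLI subcommand.

## Known limitations

- The simulator has no arterial data, so only reference-tissue measures
  can be validated; compartmental `K1`/`k3` estimation is out of scope.
- SRTM is both the generator and the assumption behind DVR = 1 + BPND;
  model mismatch (e.g. two-tissue target kinetics) is not probed.
- The lasso's 1-SE rule occasionally admits a low-|β| background region at
  some seeds — expected behavior of the rule under noise, visible in the
  reported selected-region count rather than hidden by a cutoff.
- The measure-scale threshold mapping assumes a monotone score-measure
  relationship, which holds for single-feature logistic scores with
  positive slope; multi-feature thresholds are reported on the composite
  index scale.
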