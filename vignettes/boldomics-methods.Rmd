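---
title: "Regional-parameter omics for resting-state BOLD: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional-parameter omics for resting-state BOLD: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Resting-state BOLD fMRI records spontaneous low-frequency intensity
fluctuations. In brain-tumor imaging these fluctuations carry information
about perfusion, vascular delay and local synchrony inside the lesion, even
where the usual network-analysis assumptions (intact neurovascular coupling)
do not hold. `boldomics` treats the lesion as a measurement target and
summarizes each tumor subregion by an exhaustive panel of *regional
parameters* rather than by a single index:

* **ALFF** — the mean of the one-sided amplitude spectrum
  $a(f) = 2\,\lvert X(f)\rvert / N$ over the DFT bins of a band. Using the
  band *mean* (not the sum) makes a pure tone of amplitude $A$ in a band of
  $m$ bins give exactly $A/m$, and makes values comparable across bands of
  different widths.
* **fALFF** — the band amplitude sum divided by the amplitude sum over the
  whole spectrum $(0, f_{\mathrm{Nyq}}]$, with $0/0 := 0$. A ratio in
  $[0,1]$ that indexes spectral concentration rather than raw power.
* **ReHo** — Kendall's coefficient of concordance
  $W = 12 \sum_t (R_t - \bar R)^2 / \big(K^2 (n^3 - n)\big)$
  over the time-series ranks of a voxel and its $K-1$ in-mask neighbors
  (27-voxel cube by default; 7 and 19 available). Midranks handle ties; no
  tie correction is applied, matching the classical formula (a corrected
  variant would shift the null level $1/K$ that our calibration tests pin
  down). Edge voxels use the reduced neighbor set that exists.
* **HE** — the Hurst exponent by detrended fluctuation analysis of order 1:
  cumulative sum of the centered series, non-overlapping windows at each
  scale $s$, per-window linear detrend, RMS fluctuation $F(s)$, and the
  least-squares slope of $\log F$ on $\log s$. White noise calibrates to
  $0.5$; persistent signals exceed it.
* **TSA** — the hemodynamic lag: the integer shift in TR units at which the
  voxel's Pearson correlation with a healthy-brain reference series peaks,
  searched exhaustively over $[-3, +3]$ TR. The signed correlation is
  maximized (not $\lvert r \rvert$); ties go to the smallest $\lvert
  \text{lag}\rvert$, then to the negative lag. Positive lag means the voxel
  is delayed relative to the reference.

Each parameter is computed with and without global signal regression
(the physiological meaning of the global signal is contested, so both
variants are features), and HE/TSA additionally with and without spatial
smoothing; ALFF and fALFF are smoothed by convention, ReHo never is (local
rank concordance is inflated by smoothing). That yields 14 admissible
variants. Every variant is measured in 10 frequency bands — the broad
0.01–0.1 Hz low-frequency range plus nine contiguous 0.01-Hz bins — and
averaged over 3 subregions (contrast enhancement, non-enhancement,
peritumoral edema), giving the 420-feature table
(14 × 10 × 3) with self-describing names
`<base>_<s|ns>_<gsr|nogsr>_<band>_<roi>`.

## Preprocessing conventions

Inputs are assumed co-registered; the temporal pipeline is fixed and logged:
discard the first 5 volumes, smooth (6 mm FWHM, only for the variants that
call for it), regress nuisance covariates (intercept, six motion parameters,
white-matter and CSF means, optionally the global mean), then band-filter.
Regression precedes filtering so the regression cannot reintroduce
frequencies the filter removed; the global mean excludes the tumor
subregions so the object of measurement is not regressed out of itself.

**Band definitions.** Bands are half-open $[f_{lo}, f_{hi})$ on DFT bin
frequencies; the broad band and the ninth bin close their upper edge at
0.10 Hz so the nine bins tile the broad band exactly once. With 400 retained
volumes at TR = 1 s the broad band covers bins 4–40 (37 bins), so the
expected fALFF of white noise is $37/200 = 0.185$ — one of the calibration
checks.

**Filter realization.** The band-pass is the exact spectral projection: keep
the in-band DFT bins, zero everything else. This operator is linear,
idempotent to machine precision, passes exact-bin tones untouched and
rejects out-of-band tones completely — properties a filter-after-detrend
composition cannot deliver simultaneously, because detrending a band-limited
signal re-introduces out-of-band content. The projection is algebraically
identical to an ideal filter composed with a linear detrend whose trend
basis has been orthogonalized against the passband. A conventional
least-squares detrend is still applied once per preprocessing stream before
the spectral step, which also removes the small in-band leakage of linear
drifts.

**Smoothing.** Separable discrete Gaussians with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in mm (voxel sizes read
from the affine), with edge-renormalized kernels: constant volumes pass
unchanged everywhere, and mass is conserved away from the boundary. At the
boundary those two properties are mutually exclusive; constancy wins, as in
normalized-convolution practice.

**Degenerate voxels.** Constant series (HE), zero-variance voxels or
references (TSA) yield a missing code (`NA`), never zero — a zero would bias
ROI means. ROI summaries average the non-missing in-mask voxels and only
become missing when a whole ROI is degenerate; imputation happens at
modeling time, from training data only.

## The modeling half

The table is split 7:3, stratified by endpoint, with per-class training
counts allocated by largest remainder (176 subjects give the 123/53
partition). On the training side a greedy Spearman redundancy filter visits
features by decreasing $\lvert\rho\rvert$ with the endpoint and drops any
feature whose $\lvert\rho\rvert$ with an already-retained feature exceeds
0.9 — of any redundant group, the member most associated with the endpoint
survives. Three selectors (ANOVA F-statistic top-$k$, L1-penalized logistic
at strength $C$ with $\lambda = 1/(nC)$, random-forest impurity above the
mean) feed four classifiers (ridge logistic regression, RBF-kernel SVM,
random forest, linear SVC). Hyperparameters are tuned by exhaustive grid
search with 5-fold stratified cross-validation on F1 at the 0.5 score
threshold; imputation, redundancy filtering, selection and standardization
are refit inside every fold (standardization only for the scale-sensitive
linear models). Defaults: $C \in \{0.01, 0.1, 1, 10, 100\}$; RBF
$\gamma \in \{1/(p\,\mathrm{Var}x),\ 0.01,\ 0.001\}$; forests with
100/300/500 trees at depth 3/5/unlimited. Ties take the first grid point.

Held-out evaluation reports AUROC (Mann–Whitney rank identity), AUPRC
(step integration over descending distinct thresholds — the
average-precision form, no trapezoids), and ACC/SEN/SPE/F1 at threshold
0.5. Across the selector × classifier grid the winner has the top test
AUROC, ties broken by AUPRC. Importances are model-native (impurity for
forests, absolute coefficients for linear models); RBF-kernel winners fall
back to training-set permutation importance, since a kernel machine exposes
no coefficients. The positive class is the clinically adverse label, fixing
the meaning of sensitivity and F1.

The conventional baseline scores each of the five base parameters (broad
band, no GSR, conventional smoothing) per subregion directly as a
classifier, orienting every index so AUROC ≥ 0.5 (the direction is
reported) — a 5 × 3 heatmap — and compares the best cell against the rest
with DeLong's test for paired AUROCs: placement components $V_{10}$ and
$V_{01}$ with midrank ties, their empirical covariance across models, a
normal $z$, two-sided $p$, reported next to the Bonferroni-adjusted
threshold for the 14 comparisons. Equal AUCs with zero variance resolve to
$p = 1$; unequal AUCs with zero variance are an error, not a silent
division.

## What the phantom emulates — and what it does not

The synthetic phantom generates the full input bundle: a 4D series
(405 volumes, TR = 1 s, matching the acquisition the pipeline is built
for), three disjoint subregion blocks inside a brain mask, a nuisance table
(six random-walk motion parameters plus white-matter and CSF series that
leak weakly into the voxel signals), labels and a ground-truth record.
Voxel signals are sums of

* band-limited oscillations, all filtered from a single shared broadband
  driver so that regions with overlapping bands are mutually coherent and
  circular lag shifts are recoverable by cross-correlation;
* a high-frequency (0.15–0.25 Hz) component standing in for
  cardiorespiratory content, giving the fractional measures a denominator;
* noise spectrally shaped as $S(f) \propto f^{\,1-2H}$ to a per-region
  target Hurst exponent (chosen spectrally precisely so DFA has an analytic
  expectation);
* white noise.

Geometry defaults were fixed once: a 10×10×10 grid (8×8×8 in the compact
benchmark configuration), brain mask one voxel inside the grid, 3×3×3
blocks, voxel size 3.4375 × 3.4375 × 6.5 mm from the EPI geometry
(220 mm FOV / 64 matrix, 5 mm slices + 1.5 mm gap); amplitudes 1–1.2 a.u.,
noise and Hurst-noise SD 0.5, 10% log-normal per-subject amplitude jitter.
Cohorts derive per-subject seeds deterministically from the cohort seed.

Planted effects perturb the generator, not the table: TSA effects shift a
region's lag by δ TR and HE effects shift its target exponent by δ — both
exact in feature units; ALFF/ReHo effects add coherent in-band amplitude
(approximate in feature units, attenuated roughly threefold by smoothing at
this geometry); fALFF effects shrink the high-frequency amplitude,
concentrating the spectrum without touching what ALFF, ReHo or TSA see.

The phantom has no anatomy, no motion, no scanner drift or spike artifacts,
no partial-volume structure and block-shaped lesions. Passing the
closed-loop tests therefore demonstrates that the estimators, the feature
plumbing and the model-selection machinery recover known ground truth under
realistic noise — it does not demonstrate clinical validity on patient data,
which requires the co-registration and segmentation steps this package
deliberately treats as inputs.

## Validation design and problem sizes

Four layers, all runnable from a clean install:

1. **Structural counts** — 14 variants, 10 bands, 3 subregions, 420
   features, 140 maps, the 123/53 split of 176 phantom subjects.
2. **Engine-vs-oracle equivalence** — each engine against a deliberately
   naive reference: direct DFT summation (ALFF/fALFF), the raw rank formula
   (ReHo, including ties), exhaustive lag scans (TSA), exhaustive pair
   counting (AUROC), a jackknife variance (DeLong, within 10%), and an
   independent published DeLong implementation.
3. **Calibrations** — DFA on white noise $0.5 \pm 0.1$ (median of 200
   voxels, $n = 400$); fALFF of white noise $0.18 \pm 0.02$ in the broad
   band; ReHo null within 0.01 of $1/27$; DeLong type-I error in
   $[0.03, 0.07]$ over 2000 paired-null simulations at $n = 100$.
4. **Closed loop** — 20 independent 120-subject cohorts with a 1-TR lag
   planted in the enhancement region (named through three narrow-band TSA
   features): mean held-out AUROC of the winning model ≥ 0.8 and the
   planted (parameter, band, region) signal in the winner's top-10
   importances in ≥ 80% of cohorts. A planted lag cannot distinguish the
   smoothing/GSR flags, and the redundancy filter keeps exactly one of a
   set of near-duplicate variants, so recovery is judged on (TSA,
   enhancement, planted band). Three 60-subject null cohorts must keep
   their mean test AUROC across all 12 pipelines inside $[0.3, 0.7]$ — the
   mean, because a single model's null AUROC at 18 test subjects has
   standard deviation ≈ 0.14 and would wander outside that band regularly
   even when everything is correct.

The closed loop uses the compact 8×8×8 grid: ROI summaries are provably
identical between whole-brain and ROI-restricted evaluation (a tested
bit-level equivalence), so the grid choice affects runtime, not the
measured features. `scripts/acceptance.R` recomputes layers 1, 3 and 4 from
scratch (10 closed-loop cohorts in the script) and writes them as JSON.

## Known limitations

* Integer-lag TSA cannot represent sub-TR delays; at TR = 1 s that is a
  ±0.5 s quantization.
* DFA on a narrow band-passed series measures the regularity of a
  near-oscillatory signal, not a free long-memory exponent; HE features in
  narrow bins should be read as band-wise regularity indices. The
  calibration against target exponents is run on unfiltered noise for that
  reason.
* The redundancy filter and selectors are greedy and marginal; strongly
  interacting feature pairs with weak marginals can be dropped.
* A single 7:3 split (as in the benchmarked design) has high variance at
  cohort sizes around a hundred; the closed-loop acceptance averages over
  20 cohorts for exactly that reason, and no nested cross-validation is
  attempted.
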