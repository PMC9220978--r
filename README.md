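# boldomics

Regional-parameter omics for resting-state BOLD fMRI of brain tumors.

Conventional resting-state analyses of gliomas reduce a lesion to one index
(one parameter, one frequency band, one region of interest). `boldomics`
instead measures an exhaustive panel — the amplitude of low-frequency
fluctuation (ALFF) and its fractional variant (fALFF), regional homogeneity
(ReHo, Kendall's W), the Hurst exponent (HE, by detrended fluctuation
analysis), and the hemodynamic time shift (TSA, lag of peak cross-correlation
with a healthy-brain reference) — each with and without global signal
regression and, for HE/TSA, with and without spatial smoothing (14 variants),
in 10 frequency bands (0.01–0.1 Hz plus nine 0.01-Hz bins), averaged over 3
tumor subregions (enhancement, non-enhancement, peritumoral edema). The
resulting 420-feature table feeds a radiomics-style benchmarking loop
(Spearman redundancy filter at |ρ| > 0.9, three feature selectors, four
classifiers, 5-fold cross-validated grid search on F1, held-out
AUROC/AUPRC/ACC/SEN/SPE/F1) and is compared against the conventional
single-index baseline with DeLong's test for paired AUROCs. Feature names
encode their full provenance (`tsa_ns_gsr_0.03-0.04_enhancement` = unsmoothed
TSA after global regression, 0.03–0.04 Hz, enhancement region), so importance
rankings read as statements about physiology, frequency and anatomy.

The package is aimed at neuroimaging methodologists and onco-imaging groups
who have co-registered 4D BOLD series and subregion masks and want a
reproducible, testable feature-extraction and benchmarking pipeline. A
synthetic phantom generator with known ground truth (band-limited coherent
oscillations, Hurst-shaped noise, planted lags and group effects) makes every
stage verifiable without patient data.

## Core definitions

For a voxel series $x_t$, $t = 1,\dots,N$, with one-sided amplitude spectrum
$a(f) = 2\lvert X(f)\rvert/N$:

- $\mathrm{ALFF}_{B} = \frac{1}{|B|}\sum_{f \in B} a(f)$,
  $\qquad \mathrm{fALFF}_{B} = \sum_{f \in B} a(f) \Big/ \sum_{0 < f \le f_{Nyq}} a(f)$
- $\mathrm{ReHo} = \dfrac{12\sum_t (R_t - \bar R)^2}{K^2(N^3 - N)}$ over the
  rank sums $R_t$ of the $K$ series in a voxel's 27-neighborhood
- $\mathrm{HE}$ = slope of $\log F(s)$ vs $\log s$, DFA-1 with eight
  log-spaced scales in $[4, N/4]$
- $\mathrm{TSA} = \arg\max_{\ell \in [-3,3]} \mathrm{corr}(x_{t+\ell},
  r_t)$ against the mean series of tumor-free brain (ties toward small
  $|\ell|$, then negative)

Bands are half-open on DFT bin frequencies, the nine 0.01-Hz bins tiling
0.01–0.1 Hz exactly once.

## Worked example

Generate a 40-subject phantom cohort with a 1-TR hemodynamic delay planted in
the enhancement region (named through a narrow-band TSA feature), extract the
420-feature table, and benchmark all selector × classifier combinations:

```r
library(boldomics)

cfg <- phantom_config(grid_shape = c(8, 8, 8), seed = 42)
effects <- list(list(feature = "tsa_ns_nogsr_0.04-0.05_enhancement", delta = 1))
cohort <- generate_cohort(cfg, n_subjects = 40, effects = effects)

features <- cohort_feature_table(cohort$subjects, cohort$labels)
dim(features)
#> [1]  40 422          # subject_id + label + 420 features

experiment <- run_omics_experiment(features, seed = 42)
glance(experiment)
#>   selector classifier n_selected cv_f1 auroc auprc   acc   sen   spe    f1
#> 1 f_test   lr                 30     1     1     1     1     1     1     1

head(tidy(experiment$winner), 5)[, c("feature", "importance")]
#>   feature                            importance
#> 1 tsa_ns_nogsr_0.01-0.10_enhancement     0.0749
#> 2 tsa_s_nogsr_0.05-0.06_enhancement      0.0746
#> 3 falff_s_gsr_0.01-0.10_enhancement      0.0725
#> 4 tsa_s_nogsr_0.04-0.05_enhancement      0.0724
#> 5 falff_s_gsr_0.07-0.08_enhancement      0.0690
```

The winning model separates the groups perfectly on the held-out 30% (a
1-TR lag averaged over 27 voxels is a strong effect), and its top
importances point at TSA in the enhancement region — the planted ground
truth — in the planted frequency range. The conventional baseline scores
each single broad-band index per subregion and also finds the lag:

```r
baseline <- conventional_auc_grid(features)
attr(baseline, "best")
#>   index roi         feature                           auroc direction
#> 1 tsa   enhancement tsa_s_nogsr_0.01-0.10_enhancement     1         1
```

On a phantom with one concentrated planted effect the single best index
saturates too, and DeLong's test accordingly reports no difference
(`z = 0, p = 1`); the multivariate machinery earns its keep when signal is
distributed across parameters and bands, which is what the closed-loop
benchmarks (`benchmark_recovery()`, `benchmark_null()`) quantify. Plots:
`autoplot(experiment)` (leaderboard), `autoplot(experiment$winner_report)`
(ROC curve), `plot_importance(experiment)`,
`plot_conventional_heatmap(baseline)`.

A YAML-driven command-line front end covering the same stages
(`phantom` → `extract` → `model` → `baseline`) ships in `inst/cli/boldomics`.

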