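---
title: "Methods: functional-connectivity MVPA with linear support-vector models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-connectivity MVPA with linear support-vector models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Resting-state fMRI studies of cervical spondylotic myelopathy (CSM) ask
two questions of the brain's functional connectome: can the pattern of
region-to-region coupling distinguish patients from healthy controls,
and does it carry information about a patient's clinical state — here
the Japanese Orthopedic Association (JOA) score (0–17, higher = better)
before decompression surgery, and the postoperative recovery
(`post − pre`) and recovery rate (`(post − pre)/(17 − pre)`).

`fcmvpa` implements that analysis chain as tested, reusable functions:

1. **Features.** Each subject contributes a T×R matrix of ROI time
   series. Functional connectivity is the Pearson correlation between
   every ROI pair; the strict lower triangle of the R×R matrix is
   vectorized in a fixed column-major order and Fisher z-transformed
   (`atanh`), giving R(R−1)/2 edge features — 6,670 for a 116-region
   AAL-style parcellation. Cleaning of real series (`clean_series`)
   detrends, regresses nuisance covariates, and bandpass-filters
   0.01–0.08 Hz, in that order.
2. **Edge-wise statistics.** Per edge, a linear model
   `edge ~ group + covariates` (age, sex, education, and site as the
   scan-parameter indicator); the group coefficient's t test reduces
   exactly to the pooled two-sample t test when no covariates are given.
   Benjamini–Hochberg step-up controls the FDR at q < 0.05.
3. **Classification.** Linear SVM (LibSVM defaults: C = 1, no scaling)
   under leave-one-out cross-validation. Inside every fold, a model
   trained on all features ranks them by absolute weight; the top
   fraction is selected and a new model retrained, over a grid from 5%
   to 100% in 5% steps (20 fractions). Significance comes from
   permutation tests (labels shuffled, the *entire* embedded-selection
   LOOCV rerun), with the Bonferroni family threshold 0.05/20 = 0.0025
   across the grid. Cross-site validation trains on one full site and
   tests on the other, both directions; ROC/AUC from signed decision
   values.
4. **Prediction.** Linear epsilon-SVR (C = 1, epsilon = 0.1) of the
   clinical scores, with a per-fold univariate filter: features whose
   Pearson correlation with the training labels has p < 0.05 (t
   transform, n−2 df) are kept. Performance is the Pearson r between
   assembled LOOCV predictions and actual scores, plus the RMSE;
   permutation nulls use the r ≥ and RMSE ≤ tails.
5. **Agreement.** Bland–Altman: differences `predicted − actual`, bias,
   SD (n−1), limits of agreement `bias ± 1.96·SD`, and the fraction of
   points within them.

## Why the embedded/per-fold discipline matters

The statistically load-bearing choice in this pipeline is *where*
feature selection happens. Selecting features on the full data set
before cross-validation uses each test subject's label twice and
produces spectacular, spurious accuracy on pure noise. Both selection
mechanisms here are therefore strictly fold-internal: the SVM weight
ranking is recomputed per LOOCV fold, and the SVR correlation filter
sees only training labels. The deliberately broken variants
(`loocv_classify(selection = "pooled")`,
`loocv_regress(filter_scope = "all")`) are retained as negative
controls; the test suite demonstrates that on pure-noise cohorts the
honest pipeline stays within the binomial chance band while the leaky
variants escape it (measured ≈ 0.87 versus a 0.72 upper bound for 20
subjects × 200 edges).

Two related conventions: permutation p-values are computed as the plain
proportion `#(null ≥ observed)/n_perm` (no +1 smoothing), with a floor
flag and the label `< 1/n_perm` when no null value reaches the observed
statistic; and a permutation rerun includes the selection step itself —
reusing the originally selected features under permuted labels (offered
as `perm_fixed_features = TRUE` for comparison) inflates significance
and is not the default.

## The synthetic cohort generator

The study's raw fMRI is not deposited, so validation runs end-to-end on
synthetic cohorts with known ground truth (`synthetic_config`,
`generate_cohort`). The generator emulates exactly the structure the
analyses assume:

* a shared **base correlation matrix** (Wishart draw blended with an
  equicorrelation component, average off-diagonal ≈ 0.2 — dense, weak
  coupling as in cortical FC);
* a sparse set of **discriminative edges** shifted by `disc_effect` on
  the Fisher-z scale in patients. The shifted matrix is generally
  indefinite, so the repair alternates between the PSD cone projection
  and re-imposing the shifted entries; a single eigenvalue clip would
  shrink the imposed effect and make `disc_effect` uninterpretable;
* a **per-subject Fisher-z jitter** (`subject_z_sd`, default 0.2)
  around the group matrix. Without it all subjects of a group would
  share one true connectome and no edge could carry subject-level score
  information. For patients the jitter's values at the score-linked
  edges are *pinned* through the PSD repair, because an unpinned repair
  shrinks the jitter by an amount that grows with the parcellation
  size, silently attenuating the score signal;
* **clinical scores**: preoperative JOA = baseline + affine function of
  the subject's true z values at `n_score_edges` edges + Gaussian noise
  (`score_noise_sd`), rounded to one decimal and clipped to [0, 17];
  postoperative JOA adds a random surgical gain, so recovery and
  recovery rate are *not* FC-linked by default and act as built-in
  negative controls;
* **two sites** reproducing the study's acquisition asymmetry: site 1
  with 170 usable volumes at TR 2.0 s, site 2 with 440 volumes at
  TR 0.8 s and doubled measurement noise (`site_noise_scale`); group
  sizes default to 27/11 and 26/36 patients/controls;
* **determinism**: a single master seed, split per subject by a counter
  scheme, makes cohorts bitwise reproducible and insensitive to
  evaluation order.

What the generator does **not** emulate: hemodynamics, temporal
autocorrelation (samples are drawn i.i.d. over time), head motion,
physiological noise structure, spatial atlas geometry, or realistic
effect heterogeneity. Passing tests on these cohorts therefore
demonstrate the *statistical machinery* — calibration, leakage-freedom,
recovery of planted structure — not performance on real BOLD data.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `disc_effect` | 0.3 z | group shift at discriminative edges; no effect sizes are published for this contrast, so the default is a convention in the range of reported FC case-control differences |
| `n_disc_edges` | 50 | sized for the 6,670-edge geometry (<1%); scaled-down runs use 15 so the alteration stays sparse — at a dense fraction the PSD repair distorts the imposed structure |
| `subject_z_sd` | 0.2 z | between-subject connectome variability |
| `score_signal_sd` / `score_noise_sd` | 1.2 / 1.0 points | split of the preoperative JOA variance into FC-driven and residual parts (total SD ≈ 1.56, matching the ~1.5 reported clinically) |
| `measurement_noise_sd`, `site_noise_scale` | 0.3, 2 | white measurement noise; site 2 noisier, attenuating its correlations |
| filter alpha (SVR) | 0.05 | per-edge detection limit is r ≈ 0.38 at n = 27; a score signal spread over k edges has per-edge correlation ~ attenuation/√k, so only a concentrated signal (few edges, low noise) is detectable at these cohort sizes — a genuine property of the published filtering rule, not of this implementation |

## Numerical choices

* **Selection size**: `k = floor(fraction · n + 0.5)` (round half up) —
  the unique rounding consistent with 1,001/1,668/2,001 features at
  15/25/30% of 6,670. Ties in |weight| break by ascending edge index.
* **Fisher z clipping** at |r| = 1 − 1e−7 keeps degenerate correlations
  finite.
* **Filter realization**: zero-phase forward–backward Butterworth,
  order 4. Order of operations: detrend → confound regression (confounds
  detrended the same way) → bandpass. A band covering [0, Nyquist) is
  treated as all-pass; a high cutoff above Nyquist is an error.
* **Fraction 1.0 reuses the all-features model**, so the no-selection
  analysis is reproduced bitwise.
* **Empty SVR selections** fall back to predicting the training mean
  (routine under permuted labels); a constant prediction vector has
  undefined Pearson r, reported as 0 so permutation counting stays
  defined.
* **PSD repairs** accept eigenvalues down to −1e−9 during alternation
  and finish with a clip at 1e−8 plus unit-diagonal rescale.
* **AUC** uses the average-rank (Mann–Whitney) formula — ties count ½ —
  which equals the trapezoidal area under the threshold-sweep curve.

## Problem sizes in the test and acceptance runs

The validation suites run at sizes chosen to make their statistical
assertions sharp: the leakage suite uses 50 pure-noise cohorts of 20
subjects × 200 edges; the permutation-calibration suites use 100 null
cohorts (14 subjects for classification — below that the discrete
accuracy distribution makes the permutation p visibly conservative —
and 12 for SVR) at 99 permutations; parameter recovery uses 25
replicate cohorts of 10 ROIs with `disc_effect = 0.6` on 5 of 45 edges.
The acceptance script reruns the full study at a 20-ROI, 190-edge
geometry with the original cohort layout (27/11 and 26/36) and 99
permutations: large enough that every stage operates in its validated
sensitivity regime, small enough to complete in minutes.

## Known limitations

* The per-fold univariate filter is the published selection rule for
  SVR, but at 26–27 patients it keeps ≈ alpha · n_edges false edges per
  fold; with thousands of edges the true signal must be strong and
  concentrated to survive. The package reports honest nulls in that
  regime rather than compensating.
* Balanced LOOCV is pessimistically biased at chance (each training
  fold is unbalanced against the held-out class); on pure noise the
  mean accuracy sits slightly below the majority-class rate. This is a
  property of the design, visible in the leakage suite.
* RMSE scale conventions differ between studies; both native-unit and
  per-fold min–max-scaled labels are supported
  (`label_scaling = "minmax"`), and the two are not comparable.
* Bland–Altman limits use the classical 1.96 multiplier, not a
  small-sample t correction, and the difference direction is fixed as
  `predicted − actual`.
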