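---
title: "Reproducibility and discriminability of fMRI brain patterns: models and methods"
author: "sparseMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility and discriminability of fMRI brain patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind **sparseMVPA**, the
choices made where the design was genuinely open, and the limits of what the
synthetic validation can show. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` compute.

## 1. The experiment and its data model

The analysis targets an event-related fMRI experiment with four stimulus
conditions — semantically congruent audiovisual (picture + spoken word),
incongruent audiovisual, unimodal picture, unimodal speech — and two
balanced semantic categories ("old people" vs "young people"). Each of the
320 trials (80 per condition) lasts 10 s and presents four stimulus
repetitions at 1, 2, 3 and 4 s after trial onset, each lasting 0.6 s.
Volumes are acquired at TR = 2 s, so a trial spans 5 samples and a subject
contributes a 1600 × V data matrix across two runs (two conditions per run,
trials interleaved). `ExperimentDesign()` encodes this structure;
`FmriExperiment` (a `SummarizedExperiment` with voxels as features and
samples as columns) carries the matrix, the event table, per-sample
trial/condition/category labels, voxel coordinates and — for synthetic data
— the planted ground truth.

Sample times are 0-based within a run (rows of a trial at 0, 2, 4, 6, 8 s
from trial onset). A sample is "stimulated" when its acquisition time falls
in `[first onset, last onset + stimulus duration)` = [1, 4.6) s, i.e. 2 of
the 5 samples per trial. Within-trial time points are indexed t = 1..5
(offsets 0..4).

### Which time point is "semantic"?

The stimulus repetitions end 4.6 s into the trial and the canonical
hemodynamic response peaks ~5 s after a stimulus, so the evoked response —
and with it any category information — is near zero at t = 1–2, at roughly a
quarter of peak at t = 3 (4 s), and peaks around t = 4–5 (6–8 s). The
acquisition closest to "6 s after the first stimulus onset" is t = 4, and
that is the default time point for decoding features and group contrasts
(`decodeT`, `statT`); both are parameters, and pattern statistics are always
computed over the full `tPoints = 1:5` grid so the temporal profile is
visible in every report.

## 2. BOLD regressors

Two regressors are built per subject from the schedule (`boldRegressors`):

* the **stimulus function** (1 at stimulated samples, 0 elsewhere) convolved
  with a double-gamma HRF gives the *simulated BOLD response* $h_s$ —
  activation information only;
* the **labeled stimulus function** (+1 for "old", −1 for "young", 0
  elsewhere; for incongruent trials the sign follows the face picture)
  convolved with the same kernel gives the *labeled BOLD response* $h_l$ —
  category information.

Convolution is causal and per run (no bleed across run boundaries). The HRF
default is the conventional double-gamma: response gamma (shape 6, scale
1 s), undershoot gamma (shape 16, scale 1 s), undershoot weight 1/6, 32-s
support, normalized to unit peak; all parameters are exposed
(`doubleGammaHrf`).

## 3. Preprocessing

Three matrix-level steps, in the fixed order mask → per-run z-scoring →
per-run linear detrending (`preprocessDataset`). Z-scoring uses the
population (1/N) variance — a documented constant, as the convention is not
universal — and maps within-run-constant voxels to zero with a warning.
Detrending removes the least-squares line per voxel per run; residuals are
orthogonal to the intercept and the time index. Motion correction, slice
timing, coregistration and spatial normalization are upstream of this
package.

## 4. Two-stage voxel selection

Per condition, the 400 rows are split into 4 trial-aligned folds of 20
trials (contiguous blocks in time order — deterministic and reproducible;
the fold scheme is not otherwise constrained). For fold $i$, the remaining
300 rows train the selection:

1. **Activation screening**: Pearson correlation of each voxel's training
   series with $h_s$; top `kActivated = 1500` by $|r|$ (zero-variance voxels
   get $r = 0$; ties break by voxel index).
2. **Sparse-representation selection** (`sparseSelect`): for `nRounds`
   rounds, draw `subsetSize` voxels uniformly without replacement and solve

   $$\min_w \|w\|_1 \quad \text{s.t.} \quad \|A w - h_l\|_\infty \le \varepsilon,$$

   accumulating $|w|$; rank by the mean $|w|$ over the rounds in which a
   voxel was drawn (never-drawn voxels score 0) and keep the top
   `kInformative = 500`. Because $h_l$ is category-signed, voxels that help
   represent it sparsely are category-discriminative.

### The linear program and its solver

`l1MinFit` solves the program above by variable splitting
($w$, $t \ge |w|$) with a Mehrotra predictor–corrector primal-dual
interior-point method (C++/Armadillo). The Newton system is reduced to an
$n \times n$ Schur complement on $w$, so cost scales with the subset size,
not with the constraint count. With $\varepsilon = 0$ the constraint becomes
$Aw = y$ and a standard-form variant with an $m \times m$ normal-equations
solve is used. Tolerances: relative duality gap and scaled residuals below
`tol = 1e-8`; a stagnation exit accepts the iterate when progress stops at a
relative gap below 1e-4 (the coefficients feed a *ranking*, which is
insensitive at that scale). Infeasible programs ($\varepsilon$ below the
best achievable uniform residual of an inconsistent system) raise an
explicit error. Correctness is tested against brute-force vertex/support
enumeration on small systems.

### Free constants of the selection

The residual bound is $\varepsilon = 0.1 \cdot \max|h_l|$, raised per round
to 1.02 × the subset's least-squares uniform residual when the subset has
fewer voxels than training rows, so every round is feasible by construction
(the least-squares solution is the witness). Defaults `nRounds = 400`,
`subsetSize = 100` were chosen by simulation against ground truth: planted
informative voxels share a single category direction, so in large subsets
the L1 program concentrates weight on the single cheapest carrier of that
direction and weaker planted voxels score ~0 (recall of the planted set
plateaued near 0.75); in 100-voxel subsets every planted voxel regularly
appears without stronger competitors and wins rounds outright (recall ≈ 1,
and each LP is ~20× cheaper). All constants are `analysisParams()` fields.

## 5. Pattern statistics

For test fold $i$ of condition $d$ and selection from condition $c$,
patterns are the rows at trial offset $t-1$ restricted to the 500 selected
voxels — 20 patterns (10 per category) per test set, 4 × 4 × 4 = 64 test
sets per subject. Within each category:

* **Reproducibility index** $R = \frac{2}{n(n-1)} \sum_{i<j}
  \cos\theta_{ij}$, the mean pairwise cosine; invariant to pattern order,
  per-pattern positive rescaling and orthonormal rotation. An alternative
  reading — the cosine of the *mean* angle — is available as
  `reproVariant = "mean-angle"`; the two order any pair of pattern sets
  identically, and mean-cosine is the default.
* **Average norm** $N = \frac{1}{n}\sum_i \|x_i\|$ and the average norm of
  **difference patterns** $x(t) - x(1)$ (baseline fixed at the trial-onset
  sample, which precedes any evoked response).

Averaging over folds yields 4 × 4 × 2 = 32 mean indices per time point and
subject.

### ROI analysis

`roiSelect` marks, per condition, the `roiM = 3000` voxels most correlated
with $h_s$ over all 80 trials of that condition, intersects the four sets,
and keeps voxels inside a cubic Talairach ROI with *closed* bounds
(boundary coordinates are included). Defaults are the left/right STS/MTG
cubes centered at (∓55, −40, 7) with half-width 15 mm. Reproducibility and
norms are then computed per condition over all trials.

## 6. Decoding

Feature vectors are the selected voxels' values at `decodeT` (raw, or
normalized to unit length to discard norm information). For each selection
(condition × fold) and each train/test condition, a linear SVM (libsvm via
e1071; hinge loss, L2 penalty, `C = 1`, no internal rescaling) is trained on
the 60 training trials and scored on the 20 held-out trials; a decision
value of exactly 0 resolves to the first category for determinism. Fold
averaging gives the 4 × 4 accuracy grid per variant, plus the overall
balance of predicted labels.

## 7. Group statistics

* `wilcoxonSignedRank`: exact paired signed-rank test. Zero differences are
  dropped (Wilcoxon's original treatment), ties get midranks, and the exact
  null distribution over all $2^n$ sign assignments is computed by the shift
  algorithm on doubled midranks for $n \le 25$ (normal approximation with
  tie correction and continuity correction above). One- and two-sided
  p-values are always both reported; directional contrasts (congruent >
  unimodal) are read from the one-sided column.
* `pairedT`: paired t-test with an explicit error on zero-variance
  differences.
* `rmAnova`: one-way repeated-measures ANOVA with subject as a blocking
  factor, df = (k−1, (k−1)(n−1)); an exactly zero condition sum of squares
  reports F = 0.
* `multipleComparisons`: all pairwise paired tests with Holm step-down
  adjustment (default — controls familywise error without sphericity
  assumptions); degenerate all-zero pairs report p = 1.

## 8. The synthetic-data generator

`generateSubject` emulates the experiment with known ground truth. Voxel $v$
of trial $j$ (condition $c_j$, category $g_j$) has noiseless amplitude

$$\mathrm{amp}_{jv} = \alpha\, a_v + \mathbb{1}[v \in \mathcal{I}]\,
  \mathrm{sign}_v\, \beta_{c_j}\, s_v\, (1 + \epsilon_j), \qquad
  \epsilon_j \sim N(0, \sigma_{c_j}),$$

where $\mathcal{I}$ is the planted informative set (60 voxels, half
preferring each category), $a_v, s_v$ are fixed per-voxel loadings and
$\epsilon_j$ is a *trial-level* multiplicative jitter on the category
pattern. The amplitude scales the within-trial convolution of the trial's
stimulus function with the HRF; responses are confined to their trial (no
inter-trial carry-over), so with zero noise and zero dispersion the trial
patterns within a condition and category are exactly equal — giving the
degenerate limits the tests assert. Baseline (100), per-run linear drift
(sd 1) and i.i.d. Gaussian noise (sd 1) are added on top.

Dispersion is modeled multiplicatively on the *category direction* because
the reproducibility index measures angles: $\sigma_c$ moves within-class
angles without changing expected amplitudes, reproducing the studied
dissociation (congruent stimulation stabilizes pattern direction while
norms stay flat). Defaults: $\sigma = 0.1$ (congruent), 0.5 (incongruent),
0.6 (picture, speech); $\beta_c = 1.6$ for all conditions.

**SNR design.** Loadings are $a_v \sim U(2.2, 2.8)$ for informative voxels
vs $U(0.2, 1.0)$ elsewhere, $s_v \sim U(0.7, 1.3)$, activation amplitude 2,
noise sd 1 — chosen once by a design-time power scan so that (i) screening
retains planted voxels despite the variance penalty their category signal
pays in the correlation with $h_s$, (ii) the dispersion contrast is
detectable in a single subject's averaged grid, and (iii) decoding stays off
ceiling for the unimodal conditions. Modeling informative voxels as strongly
stimulus-driven is an assumption: in real data category-selective voxels
need not be the most activated, and screening could then discard them.

Coordinates place 30 informative voxels uniformly inside each STS/MTG cube;
all other voxels are scattered uniformly in a brain-sized box excluding both
cubes, so ROI membership is exactly known.

**What the generator does not emulate:** spatial autocorrelation,
physiological (cardiac/respiratory) noise, motion artifacts, inter-trial
hemodynamic overlap, subject-varying HRFs, or informative voxels with
heterogeneous (non-collinear) category directions. Passing tests therefore
validate the pipeline's mechanics and its sensitivity under the planted
model, not performance on real recordings.

## 9. Problem sizes for simulation studies

The reference protocol (6000 voxels, 1500 activated, 500 informative) runs a
subject in about half a minute; simulation studies that need hundreds of
subject-level runs use `deskScaleProtocol()`: 800 voxels, screening to 200
(the same 25%), selecting 80 via 60 LP rounds of 40-voxel subsets, ROI
intersection over the top half per condition. The experiment design — 320
trials, 1600 samples, 4 folds — is never reduced. At this size a full
subject analysis takes a few seconds, so the packaged studies (20-seed
parameter recovery, 20 × 9-subject null calibration) complete in minutes.
The desk geometry gives the planted set only 80 slots for 60 planted voxels
(the reference protocol has 500 for 60), so planted-voxel recall is assessed
at the reference scale.

## 10. Known limitations

* The interior-point solver returns one optimum of a possibly non-unique
  optimal face; coefficient *values* at degenerate optima may differ across
  BLAS builds even though the objective (and in practice the ranking) is
  stable.
* The exact Wilcoxon two-sided p assumes the symmetric reflection rule;
  other conventions (doubling the one-sided p) differ in tied samples.
* ROI analysis uses coordinate cubes only; no atlas lookup.
* With very low noise, correlation screening saturates (all stimulus-driven
  voxels approach $|r| = 1$) and the activated ranking degenerates to
  tie-breaking; the degenerate-limit test therefore screens all voxels.
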