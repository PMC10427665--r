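---
title: "Label-map morphometry for neonatal brain age: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-map morphometry for neonatal brain age: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neobrainage)
```

## The problem

Between roughly 29 and 45 weeks postmenstrual age (PMA) the human brain
changes faster than at any later time: regional volumes grow at different
rates and the cortex folds dramatically. A model that predicts PMA at scan
from an MRI-derived measurement — "brain age" — is useful both as a
maturational index and, through the gap between predicted and true age, as a
screening signal. This package implements the tabular half of such a
pipeline: it starts from a multi-region segmentation label map (87 regions
by default, following the DRAW-EM neonatal parcellation layout), extracts
two per-region features, regresses PMA on them, and attributes the
prediction to regions via permutation feature importance (PFI).
Segmentation itself is upstream and out of scope; label maps are inputs.

## Features

For a label volume with regions $r = 1..R$ (label 0 = background):

* **Relational volume**: $\mathrm{RV}_r = |r| / \sum_s |s|$, voxel count
  over the summed voxel count of all nonzero structures. Dividing by total
  structure volume rather than intracranial volume makes the feature a
  composition: $\sum_r \mathrm{RV}_r = 1$ exactly (asserted to 1e-12 in the
  tests), and head size cancels.
* **Surface-to-volume ratio**: $\mathrm{SVR}_r = \mathrm{surf}(r)/|r|$,
  where $\mathrm{surf}(r)$ counts voxels of $r$ with at least one
  *face-adjacent* (6-connectivity) neighbor carrying a different label.
  A folded structure has more surface per unit volume, so SVR tracks
  gyrification at a tiny fraction of the cost of mesh-based indices.

Three conventions the definition leaves open were fixed as follows:

* **Neighborhood**: 6-connectivity is the default and the tested contract;
  18 and 26 are available (`connectivity` argument). Face adjacency is the
  standard voxel-surface definition and the most conservative choice (a
  6-surface voxel is also an 18- and 26-surface voxel, never the reverse).
* **Volume border**: out-of-bounds neighbors count as background, so a
  region touching the field-of-view edge has a well-defined surface there.
* **Differing label**: any differing label counts, not only background —
  internal boundaries between adjacent structures are surface.

Both features are pure voxel counts: voxel spacing and affine are carried as
metadata but never enter the computation, so features are invariant to
header conventions (tested). Units: RV and SVR are dimensionless in [0, 1];
an absent region gets counts 0, RV 0, SVR 0 and an `absent` flag rather
than NaN.

## Age regression

Features are ranked by $|\mathrm{Pearson}\ r|$ against PMA **on training
rows only** and the top $k$ kept ($k = 100$ by default; constant columns
rank last with $r = 0$; ties break by scheme order for determinism).
Selection is joint across the RV and SVR families — the per-family models
exist only in the PFI analysis. Selected columns are z-scored with training
statistics (a zero-variance column gets divisor 1); standardization matters
because RV values (~1e-2) and SVR values (~1e-1) live on different scales
and the ridge prior is spherical.

The reference regressor is Bayesian ridge:
$y \mid X, w, \alpha \sim \mathcal N(Xw, \alpha^{-1}I)$,
$w \mid \lambda \sim \mathcal N(0, \lambda^{-1}I)$, with Gamma hyperpriors
on both precisions (shape/rate all $10^{-6}$, the conventional nearly-flat
choice, matching the reference implementation's defaults). Precisions are
re-estimated by evidence maximization (MacKay fixed point with the
effective-parameter count $\gamma$), coefficients by the corresponding ridge
solve through the SVD; convergence is declared when the L1 coefficient
change drops below 1e-3 (300 iterations cap). The implementation was
verified against scikit-learn's `BayesianRidge` on a fixed fixture —
coefficients and intercept agree to ~1e-7 — and those externally computed
values are frozen in the test suite as the oracle.

Alternative backends behind the same `regressor_kind` interface:
closed-form linear-kernel ridge (unit penalty, response centered since the
kernel machine has no intercept), elastic net via glmnet (penalty 1, mixing
0.5 — the common defaults), and a deterministic least-squares
gradient-boosted stump ensemble (100 stumps, learning rate 0.1, no
subsampling). SVM and MLP backends were **not** implemented: no suitable
library exists in the supported offline environment, and re-implementing
either adds nothing to the scientific core. All shipped backends are
deterministic, serialize to JSON, and reload prediction-stable.

### Metrics

`evaluate()` reports MAE, RMSE, and **two** determination scores, because
the printed $R^2$ convention in this literature is the *squared Pearson
correlation* between truths and predictions — a quantity invariant to a
constant shift of the predictions. The test suite documents this pointedly:
predictions `truths + 1` score MAE = 1 with $r^2 = 1$. The error-based
coefficient of determination ($1 - \mathrm{SSE}/\mathrm{SST}$) is reported
alongside as `r2_cod` to remove the ambiguity. When either vector is
constant the Pearson form is undefined and `r2` is reported as 0.
Per-interval MAE uses 2-week bins spanning the truth range by default.

### Cohort splitting

`split_cohort()` shuffles **subjects**, not sessions, and assigns each
subject's sessions to the first partition (train, validation, test order)
still below target, so an infant scanned twice can never leak across
partitions. Targets for $N$ sessions at fractions $(f_t, f_v, f_e)$:
$n_t = \lfloor f_t N \rfloor$, $n_v = \mathrm{round}(f_v N)$,
$n_e = N - n_t - n_v$. This rounding rule is the one that reproduces the
canonical 334/84/140 partition of 558 scans at 0.60/0.15/0.25; the
fractions alone do not determine it and other plausible rules give 335 or
83. For single-session cohorts the targets are met exactly.

## Permutation feature importance

PFI is the drop in a fitted model's score when one feature column is
shuffled while the others stay intact, averaged over repeats (default 30).
Choices the definition leaves open:

* **Scorer**: coefficient of determination (`r2_cod`) — a score where
  higher is better, matching "drop in model score"; negative MAE is
  available via `scorer = "neg_mae"`.
* **Rows**: held-out rows, not training rows, so importance reflects
  generalization rather than memorization.
* **Per family**: `family_importance()` trains one Bayesian ridge on all RV
  columns and one on all SVR columns (no within-family top-k unless asked),
  so the strongly correlated RV/SVR pair of one region cannot mask each
  other across families.
* **Rescaling**: negatives clipped to 0, then division by the maximum. This
  keeps true zeros at zero and maps the strongest region to 1; min–max
  rescaling would instead force the weakest region to exactly 0, inventing
  a hard zero the data does not support. Rescaling is idempotent and
  ranking-preserving (property-tested).

The shuffle stream is a single seeded generator, features in model order and
repeats innermost, so reports are bit-reproducible. A known caveat is
baked into the tests: duplicating an informative column dilutes the
importance of each copy, so correlated features share credit — PFI ranks
regions, it does not partition variance.

## Synthetic data: the stated world

Two generators make every downstream stage testable without clinical data.

**Phantoms** (`generate_phantom`): an ellipsoidal "brain" mask is
partitioned into $R$ regions by a capacity-constrained power diagram —
voxels go to $\arg\min_i (d_i^2 - w_i)$ with weights iterated (damped 0.6,
then 0.3 after 20 steps, 60-step cap, best iterate kept) until realized
shares track targets $\mathrm{softmax}(g_r (a - 37))$ for age $a$ and
growth coefficients $g_r$. Plain nearest-centroid assignment cannot hit
prescribed shares, which is why the weighted variant is used. Defaults:
regions 1–10 carry growth coefficients ±0.05…±0.025 per week (alternating
sign, so the compositional constraint does not induce a spurious cohort
trend); regions 11–15 are "cortical": their distance field is modulated by
a sinusoidal corrugation (wavelength 4 voxels) with amplitude
$0.02\,(a - 29)$ per week, raising surface count with age while leaving
their volume share flat — fold and growth regions are deliberately
disjoint so each planted trend is verifiable in isolation. Optional
boundary noise flips a fraction of between-structure surface voxels to a
neighbor's label. Geometry (centroids) is controlled by `layout_seed`, kept
fixed across a cohort so region identities persist; per-subject seeds drive
only the noise. Share convergence is ~2–3% relative at 12 regions and
~15% worst-region at 87 regions on a 32³ grid — a voxel-quantization floor,
not an iteration failure; the planted trends survive it by an order of
magnitude. Ages are uniform over [29, 45] weeks, the neonatal scan window.

Phantoms are geometric, not anatomical. A green phantom test establishes
that extraction, regression, and PFI respond correctly to volumetric and
surface-complexity trends of realistic magnitude; it says nothing about
segmentation accuracy, partial-volume effects, or real cortical geometry.

**Tabular cohorts** (`simulate_feature_table`): RV rows are Dirichlet draws
(concentration $50\,e^{g_r(a-37)}$, $g_r = \pm 0.03$ per week for
informative regions, alternating sign), so each row sums to 1 exactly like
real RV. Informative SVR columns follow $s_0 + \beta\,(a + e)$ with
$e \sim \mathcal N(0, \sigma^2)$ and $\sigma$ (`noise_sd`) expressed **in
weeks**: inverting one feature predicts age with error sd $\sigma$, so the
univariate oracle MAE floor is $\sigma\sqrt{2/\pi}$ in closed form. The
default $\sigma = 0.5$ weeks puts that floor at ≈ 0.40 weeks; with ten
informative features the fitted pipeline averages the noise down and lands
well under it (≈ 0.15–0.20 weeks at n = 300), which is what the acceptance
check asserts (MAE ≤ 0.6, squared-Pearson $r^2$ ≥ 0.9 on a held-out 25%).
Non-informative SVR columns are pure noise of comparable magnitude
($\beta\sigma$).

## Numerical choices and degenerate inputs

* NIfTI-1 I/O is a built-in minimal reader/writer (single-file
  `.nii`/`.nii.gz`, uint8/int8/int16/uint16/int32/float32/float64, both
  endiannesses on read, int32 little-endian on write), because no NIfTI
  package exists in the supported environment. Any affine is accepted;
  only `pixdim` is retained. Values must be integral within 1e-6 after
  slope/intercept scaling; anything else errors rather than silently
  rounding a probabilistic map.
* All-background volumes: `region_volumes` returns an empty map;
  `relational_volume` errors ("no structures present") since the
  composition is undefined.
* Dice of two empty masks is defined as 1 (perfect agreement on absence).
* `surface > volume` is rejected as geometrically impossible rather than
  clamped.
* Seeds: every stochastic operation takes an explicit seed, uses an
  isolated RNG state (caller's `.Random.seed` is saved/restored), and
  derives child seeds below $2^{31}$.

## Known limitations

* The 87-entry region-name table mirrors the DRAW-EM layout but a few
  high-numbered labels carry best-effort names; integer ids are
  authoritative and unknown ids print as `region_<id>`.
* Elastic net and kernel ridge run at fixed default penalties — the
  comparison they support is qualitative (interface parity), not a tuned
  benchmark.
* PFI credit-sharing among correlated features (above) means "low
  importance" does not imply "no information".
* Accuracy numbers on real cohorts are not reproduced here: they depend on
  the upstream segmentation and the cohort itself. The package's claims are
  the property-level ones its tests compute.
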