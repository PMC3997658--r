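---
title: "Seed-network resting-state connectivity analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-network resting-state connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis model

`rsfcnet` implements a hypothesis-driven analysis of resting-state functional
connectivity (RSFC) in an a-priori network of brain regions. The network is a
set of named nodes, each a 5-mm sphere centred on a fixed MNI peak coordinate;
the built-in `"isa"` network is a five-node introspective socio-affective
circuit (subgenual cingulate, anterior cingulate, left amygdala, precuneus,
dorsomedial prefrontal cortex) and `"control"` is a four-node left-lateralized
language circuit used as a specificity control. Analyses proceed per edge —
every unordered node pair — through the following stages:

1. **Preprocessing.** The first `n_discard` frames (default 4) are dropped,
   volumes are smoothed with a 5-mm FWHM Gaussian kernel, and each voxel (or
   node) time series is residualized against a nuisance design: the six
   rigid-body motion parameters, their first backward differences (first frame
   set to 0), mean grey-matter / white-matter / CSF signals, and (order 2,
   default) the element-wise squares of all fifteen — 31 columns including the
   intercept. The residuals are band-pass filtered to 0.01–0.08 Hz.
2. **Extraction.** Each node's representative series is the *first
   eigenvariate* of its sphere's voxel series: voxel series are mean-centred,
   the leading right singular vector is scaled to unit variance, and its sign
   is fixed so that it correlates non-negatively with the sphere's mean
   series. An optional grey-matter mask restricts the sphere.
3. **Connectivity.** Per subject, Pearson correlations between node series
   are mapped through the Fisher transform `z = atanh(r)`, giving one
   subjects × edges table per network.
4. **Site deconfounding.** Multi-site cohorts are adjusted per edge by a
   saturated site × diagnosis decomposition in sum-to-zero coding: the site
   main effect and the site-by-diagnosis interaction are subtracted, the
   intercept and diagnosis components retained. In a balanced design (equal
   patients and controls per site) this equals subtracting cell-wise site
   deviations, and the pooled group difference of adjusted scores equals the
   unweighted mean of within-site differences. A constant added to one site
   shifts all adjusted values by a *common* constant (the retained grand
   mean), so every contrast is invariant.
5. **Inference.** The group difference of mean z per edge is tested by a
   Monte-Carlo permutation test: 10,000 uniform relabellings preserving group
   sizes, the same seeded permutation sequence shared across edges (this
   preserves cross-edge dependence), and the add-one estimate
   `p = (1 + #[|t*| ≥ |t|]) / (n_perm + 1)`, which can never be exactly 0.
   Benjamini–Hochberg FDR correction is applied across the tested network's
   edges only; each network is corrected separately. Cohen's *d* with pooled
   SD is reported per edge, computed on the site-adjusted scores (the same
   data the test sees).
6. **Within-group coupling and classification.** Each group's mean z per
   edge is tested against zero by a sign-flip permutation test with FDR. A
   significant group difference is then classified:
   `hyperconnectivity_of_positive_coupling` (positive shift on an edge
   positively coupled in the reference group), `loss_of_anticorrelation`
   (positive shift on an edge significantly negative in the reference group),
   or `hypoconnectivity` (negative shift).
7. **Clinical analyses.** Patients are split at the sample median of illness
   duration and of onset age (`value ≥ median` forms the long/late group,
   matching the convention that a duration equal to the printed threshold
   counts as "long"); each split is compared with the identical permutation +
   FDR machinery. Symptom severity (BDI) is related to edge connectivity by
   Spearman rank correlation with average-rank ties, permutation p-values for
   n < 30 and the asymptotic t-approximation otherwise, FDR across edges.
8. **Motion QC.** Per subject: DVARS (RMS frame-to-frame intensity change
   after rescaling the series to in-mask mean 100), framewise displacement
   (`Σ|Δtrans| + 50 mm · Σ|Δrot|`) and an RMS displacement summary
   (`sqrt(mean(c(Δtrans, 50·Δrot)²))`). The literature mixes several RMS
   conventions; the formula used here is a package convention and is recorded
   in every run manifest. Groups are compared by Welch t and Wilcoxon
   rank-sum tests, overall and per site.

## Key tunable parameters

| parameter | default | meaning |
|---|---|---|
| `radius_mm` | 5 mm | VOI sphere radius; "within 5 mm" is a closed ball on voxel centres |
| `n_discard` | 4 frames | scanner saturation frames dropped |
| `fwhm` | 5 mm | Gaussian smoothing kernel |
| `band` | 0.01–0.08 Hz | Butterworth order-4 passband, zero-phase (forward–backward) |
| `nuisance_order` | 2 | 1 = 15 base regressors, 2 = plus their squares |
| `n_perm` | 10,000 | Monte-Carlo permutations |
| `alpha` | 0.05 | FDR level; posterior threshold is `1 − alpha` |
| `tail` | two-sided | conservative default; a directional test is available |
| `head_radius` | 50 mm | rotation-to-mm conversion for FD/RMS |

Two genuinely open design points are exposed as options rather than decided
silently. First, whether filtering should precede or follow nuisance
regression is not determined by the analysis narrative this package follows;
the default order is regress-then-filter, and `filter_nuisance = TRUE`
band-passes the nuisance columns before regression so the regression cannot
reintroduce filtered-out variance. Second, permutation of diagnosis labels is
by default unrestricted across the pooled, site-adjusted sample (adjust
first, then permute); `within_site = TRUE` restricts relabelling to sites for
a stricter exchangeability argument.

## The synthetic cohort generator

No patient data ship with this package; every stage is validated against a
generator with known ground truth. A `cohort_spec()` describes a multi-site,
two-group cohort; the defaults emulate a two-site study: site 1 (TR 2.2 s,
250 frames, 30 patients + 30 matched controls), site 2 (TR 2.0 s, 156
frames, 27 + 27), ~3-mm voxels on a shared analysis grid — the common
stereotaxic space data occupy after spatial normalization.

Per subject, each edge's true connectivity on the Fisher-z scale is

```
z_edge = atanh(group target) + site offset + N(0, subject_sd²)
```

with `subject_sd = 0.15` and site offsets ±0.05 by default. The implied node
correlation matrix is projected to the nearest positive semi-definite
correlation matrix (eigenvalue clipping at 1e-8, diagonal renormalization;
the generator refuses targets whose projection moves any entry by more than
0.05). Band-limited latent node signals are produced by filtering white
Gaussian noise to 0.01–0.08 Hz, standardizing, and mixing with the Cholesky
factor of the target matrix; at both default TRs at least 80% of latent
power lies in the passband. Volumetric records embed each node's signal in
its VOI sphere on the grid and add: white noise (SD 1 against baseline 100
and signal amplitude 1), slow polynomial + cosine drift below the passband,
three tissue-mean signals on a geometric GM/WM/CSF partition of the grid,
and a motion artifact — a smooth random spatial gain field multiplied by the
framewise displacement of a reflected-random-walk motion trace (step SDs
0.06 mm and 0.0012 rad, chosen so mean FD ≈ 0.29 mm and DVARS ≈ 1.4, the
magnitudes a moderately moving adult cohort shows). Clinical covariates are
drawn from truncated normals whose parameters are moment-matched so the
realized mean equals the published-group anchors exactly (BDI 1.33/20.12,
HRSD 16.23, onset 25.74, duration 9.09 …); for the control-group BDI the
anchor SD (2.34 at mean 1.33 on a non-negative score) exceeds what any
truncated normal can attain, so the mean is matched exactly and the SD is
the closest attainable (~1.3). Patient onset ≤ age and duration ≤ age −
onset + 1 are enforced by per-subject truncation.

All randomness flows from one master seed through per-subject child seeds
(`child_seed(seed, i)`), so a subject can be regenerated in isolation — the
pipeline streams volumetric cohorts one subject at a time in constant
memory — and batch and streamed runs are bit-identical.

**Default planted pattern.** Controls couple at r = 0.30 on all ISA edges
except a negative ACC–AmyL coupling (−0.25); patients gain coupling on
SGC–ACC, SGC–PrC, ACC–PrC, AmyL–PrC (0.38) and lose the ACC–AmyL
anti-correlation (−0.16) — standardized differences around 0.4–0.5 at the
default noise level, the range reported for this contrast in the literature
the network model comes from. The language control network is null (r = 0.2
in both groups). The generator exposes group targets directly in correlation
units; there is no printed generative anchor in those units, so effect sizes
are planted via `calibrate_effect()`, which Monte-Carlo-estimates (with
common random numbers, so the response slope is nearly noise-free) the
between-subject SD of *measured* z and the measured-scale response to a
latent shift under the same measurement path, and converts a standardized
difference d into the latent z shift that realizes it.

**What the generator does not emulate:** biophysical BOLD dynamics,
anatomy, susceptibility or physiological (cardiac/respiratory) artifacts,
non-Gaussian noise, and site differences beyond an additive connectivity
offset and acquisition length/TR. Passing tests therefore demonstrate the
*statistical machinery* — calibration, error control, effect recovery — not
robustness to every property of real scanner data.

## Numerical choices

- Sphere membership is decided on voxel-centre distances through the grid
  affine; the ball is closed (≤ radius), so boundary voxels are included
  deterministically. A 5-mm sphere on a 3-mm grid with the peak on a voxel
  centre contains 19 voxels.
- The band-pass is an order-4 Butterworth applied forward and backward
  (zero phase) with odd-reflection padding of one period of `f_low` (or
  `frames − 1` if shorter); series are demeaned first, which removes the DC
  transient entirely. Passband sinusoids retain ≥ 90% amplitude, stopband
  (≥ 2 × f_high) ≤ 10%.
- Nuisance columns that are constant or collinear after mean-centring are
  pruned with a warning; a design with at least as many columns as frames is
  refused rather than silently producing rank-deficient residuals.
- The restricted volumetric path (`restrict_smoothing = TRUE`) evaluates the
  separable truncated-Gaussian smoothing kernel only at sphere voxels via a
  sparse weight matrix; it is algebraically identical to smoothing the full
  volume and subsetting (a unit test asserts equality) and makes streaming
  large cohorts cheap.
- Degenerate inputs fail loudly by design: |r| ≥ 1 − 1e-12 edges raise
  (silent clamping hides duplicated-series bugs), all-zero VOIs raise, a
  site containing only one diagnosis raises (site and diagnosis effects are
  then inseparable).
- Correlation targets are capped at |r| ≤ 0.95, and per-subject target
  matrices are PSD-projected with tolerance 1e-8.

## Validation problem sizes

The test suite validates the statistical properties at desk-scale problem
sizes chosen to estimate each property with useful precision: permutation
p-values are compared with full enumeration at 4+4 subjects (70 partitions,
20 instances); type-I error is pooled over 200 null two-site ROI-level
cohorts (8+8 per site, 120 frames, site offsets ±0.2) and must fall in the
95% binomial band around 0.05; FDR is checked on 200 mixed cohorts (3 true
edges at Δz = 0.4, 7 null, 20/group); effect recovery plants d = 0.45 at
57/group and 150 frames and compares 100 replicates against the noncentral-t
power (~0.67); and a 20-seed volumetric study (2 sites × 12+12, 154 frames,
34k voxels) plants a large (d = 1.5) hyperconnectivity pattern on the five
ISA edges of interest — including a control-group anti-correlation on
ACC–AmyL — and requires the pipeline to recover exactly that pattern. For
these property checks of the inference machinery the ROI-level cohorts are
measured directly (ROI records carry no artifacts, so the nuisance stage is
orthogonal to what is being estimated); the volumetric study exercises every
stage.

One caveat is worth stating because it follows from the arithmetic of FDR
itself: requiring *exactly* the five planted edges in a 5-true/5-null
network at q ≤ 0.05 leaves roughly a 10–15% chance per run that some null
edge slips under the step-up threshold (plus ~α for the six-edge null
control network), so even a perfectly calibrated pipeline fails the
"exact pattern" requirement in a nontrivial fraction of seeds. The 20-seed
study reports how many seeds recover the exact pattern; recovery of the five
planted edges themselves is essentially certain at d = 1.5.

## Known limitations

- Spatial preprocessing (realignment, normalization, slice timing) is out of
  scope: volumes are assumed to be in a common space, with motion parameters
  supplied alongside.
- The site adjustment targets balanced designs; unbalanced cells trigger a
  warning and use unweighted cell means.
- The RMS motion summary is a documented package convention, not an attempt
  to reproduce any particular published variant.
- Eigenvariate extraction assumes the sphere's leading temporal component is
  the signal of interest; strong within-sphere artifacts can capture it —
  which the nuisance regression is there to prevent, not cure.
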