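---
title: "Dual-band chlorophyll fluorescence analysis of chilling injury: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-band chlorophyll fluorescence analysis of chilling injury: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cfichill` grades green produce for chilling injury from pairs of
chlorophyll-fluorescence images at 675 nm and 750 nm. This vignette is
the package's own account of the models inside it: what each stage
assumes, which knobs matter, what the synthetic scenes do and do not
emulate, and where the genuinely open design choices were settled.

## The synthetic scene model

No public image set accompanies this problem, so the package carries a
generator whose output has the statistical structure the analysis relies
on. A scene is built multiplicatively:

* **Fruit geometry.** A superellipse (exponent 2.5, slightly boxier than
  an ellipse) with semi-axes defaulting to 0.41 and 0.155 of the frame —
  an elongated cucumber-like silhouette with axis ratio ≈ 2.6 — in a
  uniformly random orientation with a small centre jitter. Geometry
  scales linearly with `image_size`, so a 128 px frame renders the same
  physical scene as the 512 px default at coarser sampling.
* **Emission.** The fruit emits `fruit_emission_750` counts at 750 nm
  (default 39 000, about 60 % of the 16-bit range so a realistic camera
  would not clip); the background emits almost nothing (400 counts).
  The 675 nm band is the same noise-free structure multiplied by
  `band_ratio_675` (default 0.35): red emission is strongly re-absorbed
  by chlorophyll, so that band is dim.
* **Lesions.** Injury class 0 has none. Class 1 gets 1–3 spots of
  4–9 px radius (at 512 px scale; at ~0.27 mm/px this is the "spots
  under 5 mm" regime), class 2 gets 4–8 patches of 10.5–24 px. Lesions
  are darkened disks smoothed with σ = radius/3 so their edges are soft
  like water-soaked tissue; hard disks would make texture trivially
  separable. `lesion_darkening` (default 0.5) is the fractional centre
  darkening; the literature gives no quantitative lesion-contrast
  statistics, so this is a documented free parameter — 0.5 is "clearly
  visible but overlapping with noise", 0.8 is used as the
  strong-contrast condition.
* **Vignetting.** A cos⁴ radial law, the standard optics falloff model:
  smooth, low-frequency, equal to 1 at the frame centre and to
  `1 − vignetting_strength` at the corners. The field is stored with the
  sample, so tests can verify the multiplicative model is exactly
  invertible.
* **Noise.** Additive Gaussian, clipped at zero — an EMCCD at ~1 s
  exposure is read-noise dominated, and additive noise keeps the variance
  interpretable. Default sd 250 counts.

In-memory samples keep unquantised doubles; only `write_dataset()`
rounds to 16-bit TIFF.

What the generator does **not** emulate: surface warts and spines, 3-D
limb darkening at the silhouette (the rendered fruit edge is a hard
step), fungal growth, yellow discolouration, or spatially correlated
illumination drift. Passing tests therefore demonstrate that the
algorithms behave as specified on scenes with these statistics — not
that field accuracies on real fruit will match.

## Segmentation

The 750 nm histogram is dominated by the dark background: a single main
peak at the low-intensity end with a long bright tail. The Rosin
unimodal construction draws the chord from the peak to the last
non-empty bin and thresholds at the bin maximising the perpendicular
distance to it. Numerical choices: 256 equal-width bins over
`[0, max]`; a 3-bin moving average stabilises the peak location under
noise while distances are computed on the raw histogram; ties break to
the lowest intensity (the more inclusive mask); the reported threshold
is the *upper edge* of the corner bin, so the corner bin's own mixed
contents stay with the background — with a vignetting-spread background
occupying only a few bins, a bin-centre threshold would slice through
the background population itself. The argmax is invariant
to appending empty bins and equivariant under intensity scaling, and is
checked against an exhaustive distance scan. Cleanup keeps the largest
8-connected component and fills interior holes — dark lesions must stay
*inside* the mask to be analysed rather than excluded. A histogram whose
mode falls in the last non-empty bin, a flat histogram, or an image with
fewer than two occupied bins are rejected with explicit errors.

## Vignetting correction by image decomposition

The decomposition writes an image as `FI = Σᵢ IMFᵢ + R`: intrinsic mode
function images at increasing spatial scale plus a residual trend. The
corrected image is the reconstruction
`FI_corr = (FI + Σ_{i=2..k} IMFᵢ − IMF₁) / R`, `k < n`, with the
defaults `n = 6`, `k = 3`; the first IMF is excluded to suppress
high-frequency noise, and the formula is implemented literally as
printed (not as the algebraically distinct partial sum
`Σ_{2..k} IMFᵢ + R`). The result is a dimensionless ratio image, near 1
over healthy tissue, computed on the full rectangular frame and masked
downstream; the residual is clamped at `1e-6 × max(FI)` before division
so the near-zero background cannot blow up the ratio.

Envelope estimation is the genuinely open design point: the sifting
literature leaves interpolation and stopping unspecified, and
scattered-point spline surfaces are slow and ill-conditioned at
512 × 512. The package uses the fast order-statistics family, with one
refinement that proved decisive: envelopes are morphological **closing**
(moving max then min) and **opening** (moving min then max) over a disc
window, with *no* post-smoothing. Plain rank filters smear a step edge
across the window width, and any Gaussian smoothing of the envelope —
even σ = 0.5 px — re-introduces that smear; either way the fruit
silhouette leaks out of the residual, and near the boundary the
division inflates rather than flattens the fruit. Closing and opening
both reproduce a step exactly, so the silhouette stays in `R` where the
ratio needs it. The disc (rather than box) brush makes the behaviour
orientation-independent: with a box brush, fruit aligned with the image
axes lost their high-curvature tips to the opening. Remaining numerical
choices: the window starts at `envelope_window` (4 px), doubles per
mode, and is capped at one sixteenth of the shorter image side — large
enough to sweep noise and lesion-scale oscillations into the modes,
small enough that the fruit-scale trend (and its edge) stays in the
residual; sifting stops after 8 iterations or when the envelope-mean
energy falls below 1e-3 of the mode energy; borders are handled by
reflective padding. When a remainder runs out of local extrema —
routine for noise-free scenes — the remaining modes are returned as
zeros with a warning and the completeness identity still holds exactly.

One honest limitation follows: on *noise-free* scenes there is little
oscillatory content, almost everything lands in the residual, and the
correction flattens lesions along with the vignetting. With realistic
noise the lesion-scale structure rides in the modes and survives in the
ratio (lesion/healthy contrast ≈ 0.9 after correction, versus ≈ 0.6 in
the raw image). Class-separation sanity checks on noise-free scenes are
therefore run on the raw masked band.

## The 167-feature vector

Feature counts are contracts: 28 + 59 + 67 + 6 + 7 = 167 per band, 334
fused (675-band block first). Where only the counts are fixed by
convention, the canonical arrangements that produce them were adopted:

* **Haralick (28).** GLCMs at distance 1 for 0°/45°/90°/135°,
  symmetrised and normalised, after quantising the in-mask range to 32
  grey levels; pairs must have both pixels in the mask. All 14
  classical statistics per offset, summarised as mean and range over
  the four offsets. Sum variance is computed about the sum average (the
  printed 1973 formula references sum entropy — a known erratum);
  degenerate denominators (single grey level) give 0 by convention; the
  maximal correlation coefficient takes the square root of the
  second-largest eigenvalue of the transition-like matrix, guarded to 0.
* **Uniform LBP (59).** 8 neighbours on the 3 × 3 square ring, bit set
  when the neighbour is *strictly brighter* than the centre (so a
  constant region maps to the all-zeros pattern); 58 uniform patterns
  (≤ 2 circular transitions) plus one pooled bin; histogram over centres
  whose full 3 × 3 neighbourhood is in the mask, normalised to sum 1.
* **Gabor (67).** 4 frequencies geometric from 0.05 to 0.4 cycles/px ×
  8 orientations; complex kernels with σ = 0.56/f (≈ one octave),
  DC-removed and energy-normalised; responses by FFT correlation with
  reflective padding. Mean and sd of the response magnitude per filter
  (64 values) plus the global mean, global sd, and mean per-pixel total
  bank energy.
* **Intensity (6).** Mean, population sd, min, max, moment skewness and
  excess kurtosis of in-mask intensities; a degenerate distribution has
  skewness and kurtosis 0 by convention.
* **Hu (7).** The seven invariants of the masked intensity image with a
  sign-preserving log-magnitude transform `−sign(h)·log10|h|`;
  invariance under rotation and translation is tested to 1e-6/1e-8.

Normalisation is feature-wise standardisation fitted on training rows
only; test rows reuse the training statistics, and a zero-variance
training feature maps to 0 with a warning.

## Classification protocol

Linear soft-margin SVM (libsvm via `e1071`), chosen for its
one-parameter tuning surface. The cost grid spans [1e-4, 1e4] at
half-decade steps (17 points — the sampling density is a package
choice; only the range is prescribed); 5-fold stratified CV on the
training rows picks the cost, ties resolving to the smaller cost (wider
margin); the winner is refit on all training rows. Multi-class uses
one-vs-rest with the class of the largest oriented decision value — the
pairing scheme is not dictated by the problem, and one-vs-rest keeps
one hyperplane per class for inspection via `coef()`. Evaluation runs
30 replicates of a stratified 6:4 split (stratification is a package
choice over plain random splitting: it prevents empty-class folds at
small n); every replicate's split, folds and fit derive from one master
seed, so results reproduce bit-for-bit.

Rates follow the defect-detection convention: TN is the correctly
classified share of normal fruit, TP of injured fruit (TP1/TP2 for the
mild/severe classes in the three-class task), ACC the overall share;
all as percentages of the tested class.

## NCA feature ranking

Feature relevance is learned by neighborhood component analysis:
per-feature weights `w` enter a weighted L1 distance
`d(xᵢ,xⱼ) = Σ_r w_r² |x_ir − x_jr|`; soft nearest-neighbour
probabilities `p_ij ∝ exp(−d_ij)` define an expected leave-one-out
accuracy, maximised with an L2 penalty `λ Σ w_r²` by BFGS from uniform
weights (the analytic gradient is verified against finite differences
to 1e-5; rows are softmax-stabilised against underflow). Reported
importances are the squared weights normalised to a maximum of 1.
`λ` defaults to `1/n_train`. The incremental evaluation refits NCA per
replicate on the training rows only — leakage-safe, at the cost of a
ranking that varies across replicates — then scans the top-m subsets
(m = 1..100) with the full CV-SVM protocol. The selected size is the
smallest m whose mean accuracy reaches the full-feature mean minus one
standard error; the selection rule is a package convention, chosen so
that "selected" always means "statistically as good as everything".

## Accuracy comparison

Per-replicate ACC values across input types are compared by one-way
ANOVA; pairwise Fisher-LSD comparisons with the pooled MSE run only
when the omnibus test is significant at 5 % (the *protected* variant —
the gating keeps the procedure's type-I error near nominal, verified by
simulation at 1000 null datasets). Identical groups get the p = 1
convention. Letters come from maximal runs of sorted means within one
LSD of each other; inputs sharing a letter are indistinguishable.
Percentages print to one decimal; internal arithmetic is full
precision.

## Problem sizes used in the shipped checks

The test-suite and acceptance script render scenes at 96–256 px (the
geometry scales with the frame) and run the replicated-SVM study on
60/90/60-per-class datasets at 128 px — large enough that every stage
sees realistic structure, small enough to run on a laptop core in
minutes. Full-resolution 512 px scenes are used where resolution itself
is at stake (decomposition completeness). These sizes are package
choices; every function accepts full-resolution input.

## Known limitations

* The corrected ratio image compresses lesion contrast relative to the
  raw bands; classifiers recover it from texture and residual intensity
  structure, but very low-noise, low-contrast scenes are the hardest
  corner of the design space.
* The Gabor bank and the identity of the "basic intensity" statistics
  are canonical reconstructions that preserve the contracted counts —
  other banks with the same counts exist.
* One-vs-rest linear SVMs cannot perfectly separate a class lying
  between the others on a single discriminant direction; with 334
  features this is not binding in practice.
* The generator's hard fruit edge is harsher than real silhouettes; it
  was kept because an exactly constant fruit region makes the
  generator's own contracts testable, and the envelope design was made
  robust to it.
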