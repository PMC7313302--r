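---
title: "Hybrid curvelet/mutual-information registration: models and methods"
author: "curvemi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid curvelet/mutual-information registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical brain studies routinely pair an anatomical scan (MRI, CT) with a
functional one (PET), or two anatomical scans from different sessions.
Before the images can be read jointly they must be brought into the same
space. Monomodal pairs (MRI/MRI) can be aligned by intensity similarity
directly; multimodal pairs (MRI/PET, MRI/CT) cannot, because the same
tissue takes unrelated intensities in the two modalities — white matter is
bright on T1-weighted MRI but metabolically quiet on FDG-PET. `curvemi`
implements a single intensity-based affine pipeline that serves both cases,
evaluated by normalized mutual information (NMI) and the normalized
cross-correlation coefficient (NCCC).

## The pipeline

`registerVolumes()` runs five steps:

1. **Anisotropic diffusion denoising** of the moving image
   (Perona–Malik, `diffuseVolume()`). Explicit finite differences: per
   axis, forward/backward intensity differences (divided by the voxel
   size) are weighted by a conductance `g(|∇I|/κ)` and the weighted
   divergence times the time step is added. The rational conductance
   `1/(1+x²)` is the default; `κ` defaults to the 90th percentile of the
   gradient magnitudes, making the edge threshold data-adaptive. The
   default five iterations at the stability-maximal step `1/(2D)` (unit
   grid) visibly suppress noise without rounding tissue boundaries; the
   scheme conserves the voxel sum (zero-flux boundaries) and obeys the
   extremum principle. Only the moving image is filtered — the fixed image
   is the reference and is left untouched.
2. **Initial affine transform** (identity unless supplied). The transform
   model is 12-dof: translation (mm), Euler rotations (degrees, composed
   Rz·Ry·Rx), per-axis scales, and the three upper-triangular shears,
   acting about the fixed image's world centre so that rotation and
   translation are decoupled in the search.
3. **Curvelet feature extraction** (`curveletForward()`) of the fixed
   image and of the moving image under the current transform. The
   transform is applied slice-wise in 2D along the axial axis, with slices
   stacked per band: smooth Meyer-type frequency windows partition each
   slice's spectrum into dyadic coronae and angular wedges (the wedge
   count doubles every other scale; coarsest and finest scales are
   isotropic). The windows' squares sum to exactly one, so the frame is
   tight — coefficient energy equals image energy — and inversion is exact
   to machine precision. Antipodal wedges are symmetrized, keeping all
   coefficients real. Each band is stored on the bounding box of its
   frequency support, giving about 3.4x redundancy.
4. **Adaptive mutual information maximization.** Each matched band pair is
   modelled as bivariate Gaussian with maximum-likelihood estimates
   (`fitBandStats()`); its mutual information is the closed form
   `-½·log2(1-ρ²)` bits — even in ρ, so tissue maps with inverted contrast
   contribute exactly as much as matching ones. `adaptiveMI()` weights the
   band MIs by each pair's share of pooled coefficient energy, so bands
   carrying more structure dominate. The optimizer is a derivative-free
   direction-set (Powell-style) search with parameters scaled so one unit
   moves the head boundary by about one voxel, run stage-wise
   (translation → rigid → full affine) inside a coarse-to-fine pyramid.
5. **Final resampling** of the *original* (undiffused) moving image onto
   the fixed grid at cubic interpolation — denoising is an estimation aid;
   the output preserves original intensities.

All resampling is backward warping: each output voxel pulls its value from
the transformed source location (no holes); out-of-field voxels receive
the moving image's minimum, approximating background air, and are excluded
from reported metrics via the overlap mask.

## What it took to make the objective work across modalities

The energy-weighted Gaussian band MI is an effective surrogate
monomodally, but three refinements — all exposed in
`registrationControl()` — proved necessary for reliable multimodal
alignment, and each addresses an identifiable failure mode:

- **Directional emphasis** (`objectiveBands = "mixed"`). The isotropic
  lowpass band holds most of the coefficient energy, and Gaussian MI on it
  reduces to plain intensity correlation. Across modalities (centre-bright
  T1 versus ring-bright PET) that correlation peaks *away* from the true
  pose. The directional wedge coefficients locate edges irrespective of
  contrast polarity and prefer the true pose; using only them, however,
  exposes near-symmetries of the head outline (a 90°-rotated ellipsoid
  looks similar in wedge energy). The default objective is the mean of the
  full-band and directional-only AMIs: the lowpass anchors the global
  pose, the wedges decide orientation.
- **Rigidity prior** (`regularization`). Smooth head outlines admit
  (rotation, zoom, shear) combinations that map the outline nearly onto
  itself; an unconstrained affine search drifts along this family by tens
  of degrees. A Gaussian prior on log-zooms and shears (sd 0.07 each,
  weight 0.02 bits) — the same idea as SPM's regularized affine
  registration — makes the prior cost of such excursions exceed their
  spurious MI gain. The prior biases the recovered zooms toward 1 by a few
  percent; translation and rotation are unpenalized.
- **Resolution matching** (`resolutionMatch`). A sharp MRI paired with a
  PET of far coarser intrinsic resolution contributes band structure the
  PET cannot match, biasing rotation by several degrees. At each pyramid
  level the sharper image is smoothed until the two images' high-frequency
  power fractions (share of spectral power above half-Nyquist) agree. The
  match is data-driven — no modality labels — and inert for
  same-resolution pairs.

The search is confined to a documented capture range relative to the
initial transform (±15° rotation, ±20 voxels translation, zooms in
[0.85, 1.18], shears ±0.2): misalignments beyond it require a manual
initial transform, as with the standard interactive tools.

## Multi-resolution schedule

The default pyramid has two levels (×4 and ×2 smoothed decimation), with
translation → rigid at the coarse level and rigid → affine at the fine
level; full affine freedom at the coarsest level is withheld because the
heavily smoothed outline cannot disambiguate zoom/shear from rotation. A
×1 level is available (`pyramid = c(4, 2, 1)`) but is not the default: on
the validation phantoms it changes monomodal errors only in the third
decimal of a voxel while *worsening* multimodal rotation, since at full
resolution the band-content mismatch between a sharp and a blurred
modality is at its strongest. Convergence within a stage requires the
objective improvement to fall below 1e-5 bits and the parameter change
below 1e-3 scaled units after the line-search step has been refined to 0.1
units; each level is capped at 200 (coarse) / 160 (fine) line
minimizations. The moving image's features are recomputed after every
candidate transform (transform-then-decompose), because curvelet
coefficients are not equivariant under affine maps; the objective
evaluates band statistics in the frequency domain (Parseval), which is
algebraically identical to fitting the spatial coefficients and verified
against that route in the tests.

## Similarity metrics

`nmi()` implements
`2(H(If)+H(Im)) / (H(If)+H(Im)+H(If|Im)+H(Im|If))` with all entropies (in
bits) from a joint intensity histogram: 64 equal-width bins per axis over
each image's robust 0.5–99.5 percentile range, out-of-range values clamped
into the edge bins, conditional entropies via `H(A|B) = H(A,B) − H(B)`.
NMI ranges from 1 (independent) to 2 (identical); `nmi()` leaves the
histogram unsmoothed by default so identical images score exactly 2, while
`jointHistogram()` offers Gaussian count smoothing (default 1 bin) for
derivative-friendly estimates. `nccc()` is the Pearson correlation of
voxel intensities over the overlap — insensitive to affine intensity
changes and equal to 1 exactly under a positive linear relation. Both are
computed over the overlap region only after resampling, avoiding
border-fill bias.

## The synthetic phantom study

`makeBrainPhantom()` builds a deterministic piecewise-smooth head from
nested ellipsoids — skull shell, gray-matter shell, white-matter interior,
two deliberately unequal lateral ventricles — plus two fixed off-centre
blobs that break the outline's symmetry so that rotations are
identifiable. Tissue intensity tables are frozen in code (T1: white >
gray > CSF; PET-like: gray > white > CSF, blurred by a 2-voxel Gaussian to
emulate coarse scanner resolution; CT-like: dominant skull). The default
grid is 96³ voxels at 2 mm isotropic spacing (a ~150 mm head with margin
for misalignment); RIRE-like anisotropic spacings such as
1.25 × 1.28 × 4 mm are honoured end-to-end and exercised in the tests.
Gaussian noise is added at 2% of the intensity range by default, a
realistic SNR for structural brain images; an optional low-order
multiplicative bias field is available.

`makePhantomPair()` evaluates the analytic phantom at inverse-transformed
voxel centres, so the moving image carries *no interpolation error* and
registering it back should recover exactly the stored ground-truth
parameters. Multimodal pairs remap the moving image to PET-like contrast
(tissue-wise mean swap), blur it, bend it with a gamma curve (0.7), and
give both images independent noise. The seed fully determines every
phantom (Mersenne-Twister with inversion sampling, fixed explicitly for
cross-platform stability).

What the phantoms do *not* emulate: MR physics (no partial-volume mixing
beyond blur, no Rician noise floor), anatomical variability between
subjects, intensity non-uniformity beyond a low-order polynomial, and
non-rigid deformation. Passing the recovery study therefore demonstrates
the estimator's geometric accuracy under known misalignment and realistic
contrast/noise structure — not performance on clinical data.

The validation study registers ten monomodal and ten multimodal 96³ pairs
with random ground-truth misalignments (translations up to 8 voxels per
axis, rotations up to 10°, zooms in [0.95, 1.05]) and asserts median
per-axis recovery errors: ≤0.5 voxel and ≤1° monomodally, ≤1 voxel and
≤2° multimodally, with NMI never decreasing across registration in
converged runs. These sizes keep the full study within a few minutes on a
single CPU while leaving the misalignment magnitudes at their stated
values.

## Numerical choices and degenerate inputs

- Gaussian band MI saturates at 30 bits when `|ρ| = 1` (flagged), and a
  zero-variance band reports ρ = 0 with a degenerate flag rather than
  erroring — a constant image yields AMI 0.
- Entropies use base 2 throughout; NMI is base-invariant.
- The explicit diffusion scheme refuses time steps beyond its stability
  bound (equal to `1/(2D)` on a unit grid, spacing-adjusted otherwise)
  before touching the data.
- Near-integer resampling coordinates snap to exact lookups, so identity
  and whole-voxel translations are bit-exact under any interpolation
  order.
- NIfTI-1 headers store geometry in single precision; read spacings are
  snapped to 7 significant digits, so any realistic voxel size
  round-trips exactly.
- The direction-set search is fully deterministic; the `seed` argument is
  recorded in the result and governs only phantom generation upstream.

## Known limitations

- The transform model is affine; non-rigid deformation is out of scope.
- The curvelet decomposition is slice-wise 2D along the axial axis;
  through-plane structure is captured only via coefficient correlation
  across stacked slices, which is why through-plane rotation is the
  least-accurately recovered parameter.
- The rigidity prior trades a small bias in recovered zooms (toward 1) for
  robustness; studies needing unbiased scale estimates should weaken
  `regularization$weight` and supply a good initialization.
- Orientation handling normalizes volumes to an axis-aligned RAS grid;
  oblique acquisitions lose their obliqueness at load.
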