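---
title: "Detecting the glioma diffusion signature in MK-MD space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the glioma diffusion signature in MK-MD space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kurtosig)
```

## The model

Diffusion kurtosis imaging (DKI) extends diffusion-weighted MRI by sampling
several b-values per encoding direction and fitting the second-order
cumulant expansion of the signal decay,

$$ S(b) = S_0 \exp\!\left(-b\,D + \tfrac{1}{6} b^2 D^2 K\right), $$

where $D$ is the apparent diffusivity ($10^{-3}\,\mathrm{mm^2/s}$; b-values
in $\mathrm{s/mm^2}$ are rescaled so $b=1000$, $D=1.0$ contribute $-1$ to
the exponent) and $K$ the dimensionless apparent kurtosis — the degree to
which the decay deviates from monoexponential, i.e. from Gaussian
diffusion.  Averaging the per-direction estimates gives mean diffusivity
(MD) and mean kurtosis (MK).

In the joint MK–MD plane, healthy brain occupies a characteristic curved
band running from white matter (low MD, high MK) through gray matter to CSF
(high MD, low MK).  Diffuse glioma tissue — including its infiltrative rim
— carries MK–MD combinations *off* this band: moderately elevated MD with
disproportionately low MK.  `kurtosig` operationalises that observation as
a segmentation rule: learn the healthy occupancy of MK–MD space from a
reference cohort, and label every voxel whose (MD, MK) pair falls outside
it.

## The estimator

`fit_volume()` fits, per encoding direction,
$\ln S = \ln S_0 - b D + b^2 W$ (with $W = D^2 K / 6$) by linear least
squares over that direction's b-series; the single $b=0$ volume anchors
every series.  The $3\times3$ normal equations are solved in closed form on
per-voxel moment sums, which makes the voxel loop a handful of matrix
products and keeps a whole-brain fit on the default phantom below ten
seconds.  A signal-squared weighting flag is available (it counteracts the
log transform's noise amplification at high b); the default is unweighted
for simplicity and because the noiseless roundtrip is then exact to
machine precision.

This is deliberately *not* a full 22-parameter diffusion/kurtosis tensor
fit: the signature uses only the direction means MD and MK, and the
phantom is isotropic, so the per-direction route exercises everything the
pipeline consumes while remaining exactly invertible in tests.

Constraints: $D$ is clamped to $(0, d_{\max}]$ with $d_{\max} = 5$, $K$ to
$[0, k_{\max}]$ with $k_{\max} = 3$ — generous physiological ranges whose
purpose is to keep noise-driven outliers from polluting the MK–MD
histogram.  Voxels with a nonpositive signal in any volume are flagged
invalid (`NA`) rather than fitted.

Pre-smoothing (`sigma`, default 1.25 in-plane voxels) is an isotropic
Gaussian in world millimetres: the in-plane width is scaled by the voxel
size per axis so through-plane smoothing matches the in-plane extent.
Kernels are renormalised at the volume edges, so constants are preserved
exactly and `sigma = 0` is the bitwise identity.

## The signature region

`joint_histogram()` bins (MD, MK) pairs on a fixed lattice (MD 0–3.5 step
0.05; MK 0–3.0 step 0.02).  Fixed edges make subjects directly poolable;
the widths are fine enough to separate the tumor cluster from the healthy
band in phantom tests, and coarse enough that a single subject's scatter
does not fragment into empty-bin speckle.

`build_reference_occupancy()` pools the reference cohort's histograms and
marks a bin occupied when its pooled relative frequency reaches `tau`
(default $10^{-5}$), then dilates by one bin (Chebyshev).  Pooling rather
than intersecting subjects is the conservative choice — a larger occupancy
can only reduce false-positive signature voxels.  At `tau = 0` the
occupancy degrades gracefully to the pooled support — the strictest
absence-from-healthy-brain rule.  The threshold and dilation absorb
two kinds of fragility: single-voxel outliers in a finite reference
cohort, and off-by-one-bin effects at the occupancy boundary.

`derive_signature_region()` takes the complement within physiological
bounds (MD in (0.2, 3.0], MK in (0.1, 2.0]), excluding regions (near-zero
MD, extreme MK) that no plausible tissue reaches but noise artifacts
might.  `label_voxels()` then marks masked voxels whose bin lies in the
region and removes 26-connected components below `min_cluster = 10`
voxels — isolated noise voxels, not tumors.  Whether the anomalous
scatter area should be drawn per patient or fixed across patients is left
open by the source material; the package defaults to one fixed region
derived from controls (reproducible, no per-case operator input) and
offers `manual_gate_region()` to mimic per-case visual delineation.
Whether CSF should be masked out of the reference scatter is equally
unstated; the package includes it, which only enlarges the occupancy and
is therefore conservative.

## The phantom

Because no imaging data are distributed, `build_phantom()` renders a
parametric brain: nested ellipsoids for brain, cortical gray matter,
white matter and a ventricular CSF body, plus a spherical tumor (12 mm
core, infiltrative rim to 16 mm — 8 in-plane voxels) embedded in white
matter, the typical seat of diffuse glioma.  Geometry lives in world
millimetres and is rendered independently on the 2×2×5 mm DKI grid and
the 1×1×3 mm anatomical grid, reproducing the slice-thickness mismatch
between diffusion and anatomical acquisitions that makes mask resampling
a genuine error source.

Default tissue values (MD in $10^{-3}\,\mathrm{mm^2/s}$): WM (0.80, 1.00),
GM (1.00, 0.70), CSF (3.00, 0.15), tumor core (1.30, 0.45), rim
(1.10, 0.55) — typical literature magnitudes that reproduce both the
inverse MK–MD trend of healthy brain and the off-band tumor cluster.
Within-class jitter is Gaussian with sd 0.01 (CSF MD: 0.03).  The sd was
chosen relative to the bin widths so that the healthy clouds' supports are
compact and fully sampled by a three-subject reference cohort, making the
"the signature never occurs in healthy brain" property hold *by
construction* in the noiseless phantom; it under-represents the
within-class spread of real tissue, which is one reason phantom
specificity results should not be read as clinical specificity.

The forward simulation evaluates the kurtosis representation per voxel
(the phantom is isotropic, so all directions agree), verifies
$b_{\max} \le 3/(D K)$ everywhere — beyond that point the representation
is non-monotone and simulating from it would be meaningless — and applies
Rician noise: Gaussian noise of sd $\bar S_0/\mathrm{snr}$ on two
quadrature channels followed by the magnitude.  The default $b=0$ SNR of
40 is an implementer's choice typical of 3 T EPI diffusion protocols, not
a reported value.  Directions come from a spherical Fibonacci lattice
(deterministic, near-uniform, minimal pairwise angle 32.7° at $n=30$); the
$b=0$ volume is stored once rather than once per direction, matching
acquisition practice and simplifying the shared-anchor fit.

## Resampling and evaluation

`resample_to_grid()` uses world-coordinate pull-back with voxel-centre
semantics and 0-based NIfTI affines: masks by nearest neighbour (ties
broken upward, never banker's rounding, so aligned integer-ratio grids
roundtrip bit-reproducibly), scalar maps optionally trilinear.
`dice()` demands a shared grid — resampling is never implicit — and
defines the both-empty case as 1.0 with an explicit warning, so degenerate
synthetic cases are visible rather than fatal.  Automatic labels are
evaluated either on the DKI grid against the rendered DKI-grid truth, or
(default in `run_pipeline()` configs mirroring the manual-delineation
workflow: `evaluation.grid = "dki"` here, `"anat"` available) after
nearest-neighbour resampling onto the anatomical grid.

A property worth stating precisely: a nearest-neighbour pull-back
roundtrip coarse → fine → coarse is the *identity* whenever the fine grid
covers the coarse one and each coarse centre's nearest fine centre lies
closer to it than to any other coarse centre — guaranteed when half the
fine spacing is below half the coarse spacing, as it is for the default
grid pair in every axis.
Margin degradation therefore only appears in the fine → coarse → fine
direction (a sphere delineated at anatomical resolution, carried through
the DKI grid and back, keeps Dice ≈ 0.92), which is exactly the
slice-thickness effect reported for manual-VOI comparisons.

## What the tests show — and what they cannot

Problem sizes were chosen to exercise full realism where it matters and
stay fast elsewhere: acceptance-level checks run the full 64×64×24 grid
with the 151-volume scheme (three reference subjects, three noisy
repetitions), unit tests a 32×32×12 phantom with 6–8 directions.

At snr = 40 with default smoothing, median WM map errors are ~1.5 % (MD)
and ~1.3 % (MK), and the end-to-end phantom Dice is ≈ 0.86.  The missing
overlap is almost entirely the outermost rim voxel layer: smoothing mixes
their signals with adjacent white matter, and the rim→WM mixture
trajectory in MK–MD space passes through the same bins as the healthy
WM→GM partial-volume arc that the reference cohort itself occupies, so
those voxels are genuinely indistinguishable from healthy tissue in this
feature space.  This is a real property of feature-space segmentation at
coarse resolution, not an estimator artifact: a signature derived from
where healthy tissue *never* goes must surrender the partial-volume shell
where tumor and healthy signals blend.  A smaller smoothing kernel raises
the phantom Dice at the cost of noisier maps.

The phantom omits, by design: diffusion anisotropy (the pipeline consumes
only direction means), realistic cortical folding, k-space artifacts,
motion/eddy distortions, and Rician bias correction.  Passing phantom
tests therefore demonstrates the correctness of the estimator, the
occupancy construction, the labelling and the overlap arithmetic — not
clinical sensitivity or specificity, which depend on tissue heterogeneity
the phantom deliberately lacks.
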