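# kurtosig

Glioma carries a "diffusion signature": in whole-brain diffusion kurtosis
imaging (DKI), the joint distribution of mean diffusivity (MD) and mean
kurtosis (MK) of healthy brain occupies a characteristic band — white
matter at low MD / high MK, through gray matter, down to CSF at high MD /
low MK — while diffuse glioma tissue, including its infiltrative rim,
shows MK–MD combinations that healthy brain never produces.  Labelling
the voxels carrying those combinations segments the tumor with no manual
delineation at all.

`kurtosig` implements that analysis as a reusable R pipeline for
neuroimaging researchers:

1. **Map fitting** — per-voxel MD/MK from multi-shell DWI via the kurtosis
   signal representation
   `S(b) = S0 · exp(−b·D + b²D²K/6)`
   (per-direction log-linear least squares, shared b = 0 anchor, optional
   Gaussian pre-smoothing), with `D` the apparent diffusivity in
   10⁻³ mm²/s and `K` the dimensionless apparent kurtosis.
2. **Signature detection** — a fixed-lattice joint MK–MD histogram, the
   pooled healthy-reference occupancy (threshold `tau`, one-bin dilation),
   its bounded complement as the glioma-specific region, and voxel
   labelling with small-cluster removal.
3. **Evaluation** — affine-aware resampling between the coarse DKI grid
   and a finer anatomical grid, and Dice overlap against a reference
   segmentation (`2|A∩B| / (|A|+|B|)`).
4. **Synthetic phantoms** — parametric brain geometry with ground-truth
   MD/MK, a WM-embedded tumor sphere, a six-shell 151-volume acquisition
   (b = 0…2500 s/mm², 30 directions/shell) and Rician noise, so the whole
   pipeline is testable without patient data.

Formats: NIfTI-1 volumes, FSL-dialect `.bval`/`.bvec` gradient tables,
CSV occupancy/overlap reports, YAML pipeline configs.

## Worked example

Build a healthy reference occupancy from three simulated control subjects,
then detect the tumor in a noisy phantom case:

```r
library(kurtosig)

scheme <- make_scheme(c(0, 500, 1000, 1500, 2000, 2500), 30)
#> <dki_scheme> 151 volumes: b = {0, 500, 1000, 1500, 2000, 2500} s/mm^2, 30 directions/shell

# healthy reference cohort -> MK-MD occupancy -> signature region
refs <- lapply(1:3, function(s) {
  ph <- build_phantom(phantom_spec(snr = 40, seed = s, include_tumor = FALSE))
  fit <- fit_volume(simulate_dwi(ph, scheme), ph$brain_mask, sigma = 1.25)
  joint_histogram(fit$md, fit$mk, ph$brain_mask, source_id = paste0("ctrl", s))
})
occ <- build_reference_occupancy(refs, tau = 1e-5, dilate = 1)
#> <occupancy_mask> 329 of 10500 bins occupied (3 subjects, tau = 1e-05, dilate = 1)
region <- derive_signature_region(occ)
#> <signature_region> 5027 of 10500 bins

# tumor case: fit, detect, score
case <- build_phantom(phantom_spec(snr = 40, seed = 7))
fit <- fit_volume(simulate_dwi(case, scheme), case$brain_mask, sigma = 1.25)
#> <dki_fit> 32936 voxels fitted of 32936 masked (0 invalid)
label <- label_voxels(fit$md, fit$mk, case$brain_mask, region)
#> <seg_mask:auto> 64x64x24@2x2x5mm, 666 voxels set
overlap_report(label, case$tumor_mask_dki, subgroup_label = "phantom")
#>   case_id subgroup_label n_auto n_ref n_intersection      dice          grid_id
#> 1    <NA>        phantom    666   856            653 0.8580815 64x64x24@2x2x5mm
```

Of the 856 ground-truth tumor voxels, 653 carry an MK–MD combination
absent from the healthy reference and are labelled automatically; the
unlabelled remainder is the outermost rim layer whose smoothed signal
mixes with adjacent white matter (Dice 0.86 at SNR 40 — in the noiseless
phantom the same pipeline reaches Dice 1.0).  Apart from 13
false-positive voxels at the tumor margin, the labelled set stays inside
the tumor — the signature does not fire elsewhere in the brain.

`plot_signature_scatter(fit$md, fit$mk, case$brain_mask, region, occ,
file = "scatter.png")` renders the MK-vs-MD scatter with the healthy
occupancy shaded and the signature region outlined.

A YAML-driven end-to-end run (simulate → fit → reference → detect →
dice), writing all artifacts plus a run log:

```r
run <- run_pipeline(read_pipeline_config("pipeline.yaml"), out_dir = "out")
```

and the same from a shell via the bundled CLI
(`inst/cli/kurtosig.R simulate|fit|reference|detect|dice|run`).

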