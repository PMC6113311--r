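# subslicer

Dual-energy sub-slice reconstruction for serial block-face scanning
electron microscopy (SBEM), with a built-in Monte Carlo electron
backscattering simulator.

## The problem

SBEM alternates imaging the face of a heavy-metal-stained,
resin-embedded specimen block with shaving thin layers off it. Lateral
resolution follows the probe (5–10 nm), but z-resolution is stuck at
the minimum cutting increment, ~25 nm. Because beam penetration depth
grows with landing energy, backscattered-electron (BSE) images of the
same block face at a *low* and a *high* energy (e.g. 1.0 and 1.4 keV)
mix the stain in the first and second ~12.5-nm subsurface layer in
different proportions — enough information to unmix them.

`subslicer` is for microscopists and image-analysis people who want to
double SBEM z-resolution computationally: it calibrates the depth
response by Monte Carlo, inverts dual-energy stacks per pixel, and
budgets the electron dose that block shrinkage allows.

## The model

The background-subtracted BSE signal at a pixel for landing energy
E<sub>m</sub> is modeled as

> B<sub>m</sub> = J₀ δz Σₙ A<sub>mn</sub> S<sub>n</sub>,  n = 1…N

with J₀ incident electrons per pixel, δz the sub-slice thickness,
S<sub>n</sub> the stain density (heavy atoms/nm³) in layer n, and
A<sub>mn</sub> (nm²) an effective per-atom cross section calibrated by
trajectory-level Monte Carlo (screened-Rutherford elastic scattering,
Joy–Luo continuous slowing down). For N = 2 energies/layers the stain
densities per cut are recovered per pixel as

> (S₁, S₂)ᵀ = A⁻¹ (B₁, B₂)ᵀ / (J₀ δz),

giving two 12.5-nm sub-slices per 25-nm physical cut. Pre-processing
(background subtraction, low-to-high intensity scaling by the matrix
row-sum ratio, 1-SD noise clipping, lower-sub-slice averaging) follows
the standard chain for this kind of data; the order is enforced.

## Worked example

Calibrate a response matrix at 1.0/1.4 keV, then reconstruct a noisy
synthetic benchmark: two full-density stained cuboids (one per layer)
and one half-density cuboid spanning both layers, at 1,000
electrons/pixel/image.

```r
library(subslicer)

rmat <- build_response_matrix(1.0, 1.4, n_electrons = 5e4, seed = 1)
rmat
#> <response_matrix> 2 layers x 12.5 nm at 1/1.4 keV (nm^2)
#>             [,1]        [,2]
#> [1,] 0.007000000 0.001828148
#> [2,] 0.006210864 0.004625679
#> inverse populated; condition number 5.15

truth <- three_cuboid_model(lateral_nm = 2500)
stack <- forward_project(truth, rmat, electrons_per_pixel = 1000,
                         background_eta = rmat$provenance$background$eta)
stack <- apply_shot_noise(stack, seed = 2)
stack <- subtract_background(stack, roi = list(x = 1:12, y = 1:12))
reg3  <- attr(truth, "regions")[[3]]       # the two-layer cuboid
px <- round((reg3$center[1] + c(-0.4, 0.4) * reg3$dims[1]) / 12.5)
py <- round((reg3$center[2] + c(-0.4, 0.4) * reg3$dims[2]) / 12.5)
stack <- scale_low_to_high(stack, rmat,
                           roi = list(x = px[1]:px[2], y = py[1]:py[2]))
vol <- solve_subslices(stack, rmat)
evaluate_recovery(vol, truth)
#> <recovery_metrics>
#>  planted n_vox     peak     mean        sd separation relative_error
#>     1.62  5000 1.655323 1.611371 0.4880827   1.661470    0.021804145
#>     3.24  5000 3.271536 3.226102 0.4629553   3.277683    0.009733307
#> background: peak -0.00615, sd 0.284 over 150000 voxels
```

Reading the output: row 1 is the matrix coupling at the low energy
(layer 1 dominates, A₁₁ ≫ A₁₂ — the 1.0-keV image barely sees layer 2),
row 2 the high energy (layers comparable). The recovered histogram
peaks sit within ~1–2% of the planted densities 3.24 and 1.62
atoms/nm³, the half-density cuboid separates from background by about
half the full-density separation, and the per-voxel noise (sd ≈ 0.28
in background) is the shot noise amplified through A⁻¹, exactly as the
linear propagation predicts.

Dose bookkeeping for the matching acquisition:

```r
total_fluence(acquisition_settings(75, c(3.5, 1.5), pixel_nm = 12.5))
#> [1] 14.98107        # e/nm^2, inside the ~15-20 e/nm^2 shrinkage budget
```

A caveat worth knowing before comparing absolute yields elsewhere: the
analytic screened-Rutherford cross section used by default
overestimates elastic scattering from lead at ~1 keV several-fold
relative to partial-wave (Mott) data, so *absolute* backscatter yields
of heavily stained material come out high (e.g. `bulk_yield()` of the
3 at% Pb benchmark at 1.0 keV gives η ≈ 0.39), while calibrated
reconstructions remain self-consistent and the relative depth response
(which energies see which layer) matches the benchmark behavior. See
the methods vignette (`vignettes/subslice-methods.Rmd`) for the full
discussion.

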