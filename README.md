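# laminarkit

Equivolumetric laminar profiling, cytoarchitectural gradients, and
registration evaluation on cortical surface meshes — in R.

## The problem

High-resolution laminar image volumes (cell-body-stained histology,
quantitative MRI) carry depth structure that only becomes interpretable
when sampled *within* the cortex, along columns between the pial and
white surfaces. Because laminae change thickness with cortical folding,
surfaces placed at equal *distances* cut obliquely through layers;
surfaces placed at equal tissue *volume* fractions follow them. From the
resulting depth profiles, classic observer-independent features (central
moments) and large-scale gradients of cytoarchitectural differentiation
(diffusion map embedding of profile similarity) can be derived. The same
toolbox needs to evaluate the volumetric warps that move data between
histological and MRI spaces, and to build geodesic anatomical axes (such
as the iso-to-allocortical axis of the mesiotemporal lobe) with
volumetrisation and functional-connectivity profiling.

laminarkit implements all of this for users who work with NIfTI volumes,
GIFTI or text surface meshes, and plain-text per-vertex data — and it
ships deterministic synthetic generators (folded cortical sheets, laminar
volumes with known ground truth, analytic displacement fields,
axis-graded BOLD) so every pipeline is testable without any external
data.

## The core model

An intracortical surface at volume fraction α ∈ [0, 1] is placed, per
vertex, at distance fraction

    ρ(α) = (−A_p + sqrt((1−α) A_p² + α A_w²)) / (A_w − A_p),   ρ = α if A_p = A_w

where A_p and A_w are the local pial and white vertex areas — the root of
the linear-area frustum volume equation. Profiles sampled on such a stack
feed: Taubin depth-wise smoothing (λ = 0.5, μ = −0.53), geodesic Gaussian
surface-wise smoothing, central-moment features, and the gradient
pipeline (parcel averaging → partial correlation → normalised angle
`1 − acos(r)/π` → diffusion map embedding). Warp evaluation provides the
Jacobian determinant `det(I + ∂d/∂x)`, per-label Dice `2|A∩B|/(|A|+|B|)`,
and fiducial misregistration distances.

## Worked example

Build a folded synthetic cortex, plant a six-layer staining volume with a
high-density band at volume fractions 0.40–0.45–0.50, and recover it:

```r
library(laminarkit)

sheet <- make_folded_sheet(n_x = 30, n_y = 10)        # 2 mm thick, folded
vol   <- make_laminar_volume(sheet, laminar_spec(noise_sd = 2, seed = 7),
                             voxel_size = 0.1)
stack <- build_surface_stack(sheet, n_surfaces = 50)  # equivolumetric
prof  <- sample_profiles(stack, vol)                  # 50 x 300 profiles
prof  <- smooth_profiles_depthwise(prof, iterations = 2)
prof  <- smooth_profiles_surface(prof, sheet$pial, fwhm = 2)

rec <- stack$alpha[apply(prof$values, 2, which.max)]
round(c(mean = mean(rec), mae = mean(abs(rec - 0.45))), 4)
#>   mean    mae
#> 0.4490 0.0011
```

The per-vertex profile argmax lands on the planted band centre (α = 0.45)
with a mean absolute error of 0.001 — far below one depth step (1/49 ≈
0.02). Gradients and moment features follow from the same profile set:

```r
parcels <- decimate_and_parcellate(sheet$pial, 60, seed = 1)
g <- profile_gradients(prof, parcels, n_components = 5, sparsity = 0.5)
round(g$variance_explained, 3)
#> [1] 0.333 0.172 0.126 0.080 0.041

round(head(central_moments(prof)[, 1:5], 3), 3)
#>        mean   cog     sd skewness kurtosis
#> [1,] 66.570 0.484 23.147   -0.100    0.237
#> [2,] 66.074 0.483 22.352   -0.081    0.228
#> [3,] 65.904 0.482 21.868    0.041    0.134
```

The first gradient carries a third of the nontrivial spectrum; the
centre of gravity sits just above mid-depth because the deep layers of
the planted model are lighter than the superficial bands.

A command-line entry point mirrors the functions
(`inst/cli/laminarkit`): `sample-profiles`, `gradients`, `features`,
`apply-warp`, `evaluate-warp`, `resample-surface`, `axis`, `axis-rsfc`,
and `fixtures`, each writing a JSON provenance sidecar (version, config,
input digests, seed) next to its output.

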