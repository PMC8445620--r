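---
title: "Equivolumetric laminar profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivolumetric laminar profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarkit)
```

laminarkit analyses laminar image volumes — cell-body-stained histology
resampled to a 3D grid, or any scalar volume with depth structure — on
cortical surface meshes. This vignette is the package's account of the
models it implements, the parameters that matter, and the choices made
where the design was genuinely open. Everything quantitative shown here is
computed by the package's own tests and acceptance script; nothing is
quoted from external data.

## The equivolumetric model

A cortical column between a pial vertex and its corresponding white
vertex is modelled as a frustum whose cross-sectional area varies
linearly from the local pial vertex area $A_p$ to the white vertex area
$A_w$ (one third of the summed incident face areas, so vertex areas
partition the surface area). The intracortical surface at volume fraction
$\alpha \in [0,1]$ (0 = pial, 1 = white) is placed at the distance
fraction

$$\rho(\alpha) \;=\; \frac{-A_p + \sqrt{(1-\alpha)A_p^2 + \alpha A_w^2}}{A_w - A_p},
\qquad \rho = \alpha \text{ when } A_p = A_w,$$

the root of the frustum volume equation
$\int_0^{\rho} A(t)\,dt = \alpha \int_0^1 A(t)\,dt$ with
$A(t) = A_p + (A_w - A_p)\,t$. Surfaces are initialised at equidistant
depths and modulated by curvature through this area ratio only — a single
one-shot modulation using the *input* pial and white areas, not an
iterative recomputation per level, and straight per-vertex segments
between corresponding vertices (the correspondence is given; any bending
would be unconstrained). Where the pial area exceeds the white area
(gyral crowns) cumulative volume grows fastest near the pial surface, so
the half-volume surface sits *shallower* than the equidistant midpoint;
at sulcal fundi the reverse. The acceptance suite checks the closed form
against numeric inversion of the volume integral for 1,000 random
$(A_p, A_w, \alpha)$ triples at $10^{-9}$.

Whether area maps should be smoothed before computing $\rho$ is not
settled; the default does not smooth, and `build_surface_stack()` exposes
`area_fwhm` for callers who want it. An `"equidistant"` method skips the
modulation entirely and serves as the comparison baseline in the
parameter-recovery studies.

## Profiles and their processing

`sample_profiles()` interpolates the volume at every stack coordinate,
producing the K×N profile matrix that is the package's central object.
Four interpolants are available: trilinear (default), tricubic (Keys,
a = −0.5), nearest, and sinc (Lanczos-windowed, radius 4 voxels — the
option list names sinc without parameters, so the radius is a package
choice). Samples outside the volume receive the background value and a
mask bit rather than an error, because partial-coverage volumes are the
norm for high-resolution histology blocks.

Depth-wise smoothing is the shrink-minimising two-step (Taubin) scheme on
each column: $v \leftarrow v + \lambda L(v)$ then
$v \leftarrow v + \mu L(v)$, with $L$ the 1-D umbrella operator and
endpoints held fixed. The coefficients are fixed at the classic
shrink-free pair $\lambda = 0.5$, $\mu = -0.53$; only the iteration count
is exposed (default 2). $\lambda = 0.5$ annihilates the Nyquist mode
exactly, which the tests verify against the analytic transfer function
$(1+\lambda(\cos\omega-1))(1+\mu(\cos\omega-1))$.

Surface-wise smoothing is a geodesic Gaussian: weights
$w(u,v) = \exp(-d^2/2\sigma^2)$ on the edge-weighted graph geodesic
distance, truncated at $3\sigma$ and renormalised per vertex
($\sigma = \mathrm{FWHM}/2.3548$, default FWHM 2 mm). The kernel metric
(geodesic rather than Euclidean) and the truncation radius are not
dictated by any source; both are documented here as package choices. The
operator is row-stochastic, so smoothing never expands the field's range.
Geodesics are graph geodesics along mesh edges, not exact polyhedral
geodesics — the same convention the spatial-autocorrelation metric uses
("steps" along the mesh graph).

Peak counting is strict and plateau-aware: an interior run of equal
values counts once, at its leftmost index, iff the profile is strictly
greater on both flanks; endpoints never count. The strictness matters for
interpreting the synthetic fixtures (below).

## Parcellation and gradients

Meshes are decimated by farthest-point sampling on the edge-weighted
graph (the first vertex drawn from the seed), with every vertex assigned
to its nearest selected vertex by hop distance; ties break by smallest
Euclidean distance, then lowest vertex index. This gives the parcel
membership the gradient pipeline needs; a render mesh is available via
`retriangulate()` but is deliberately minimal — gradients consume parcel
membership, not triangles.

The gradient pipeline is: (1) parcel-average profiles; (2) pairwise
partial correlation across depth, controlling for the global-average
profile by least-squares residualisation (equal to the textbook
partial-correlation identity); (3) normalised angle,
$a = 1 - \arccos(r)/\pi$; (4) diffusion map embedding. The embedding
row-sparsifies to the top 10% of each row, symmetrises by averaging,
applies the anisotropic normalisation $D^{-\alpha} W D^{-\alpha}$ with
$\alpha = 0.5$, and eigendecomposes the row-normalised operator through
its symmetric conjugate — dense and deterministic, so no random
initialisation or seed is involved. Components are the nontrivial right
eigenvectors scaled by their eigenvalues (diffusion time 0); variance
explained is defined on the nontrivial spectrum. Eigenvector sign is
fixed by nonnegative correlation with parcel index. The defaults
(α = 0.5, sparsity 0.9, 10 components) follow common gradient-mapping
practice; none is prescribed by a source, and all are exposed.

One degeneracy is worth knowing about: when profiles are an exact
two-prototype mixture, the global-average profile lies inside the planted
signal span, and controlling for it collapses the graded structure to a
sign — the first eigenvector becomes a step. The planted-recovery tests
therefore override the control with a neutral constant (the
`control` argument exists for exactly this kind of call); real profile
sets are not rank-one, so the default control behaves as intended there.

## Moments

The five classic observer-independent features — mean, centre of gravity,
SD, skewness, kurtosis — are computed for each profile and for its
finite-difference derivative (10 features). The source lists the feature
names without formulas, and two readings exist: moments of the intensity
sample across depth, or intensity-weighted depth moments. The package
computes the *intensity-sample* moments (population formulas), with the
centre of gravity as the only depth-weighted feature:
$\mathrm{COG} = \sum_k \alpha_k p_k / \sum_k p_k$ (absolute derivative
for the derivative profile, on the mid-depth grid). Zero-sum profiles
have no defined COG and are flagged `NA`.

## Warp evaluation

Displacement fields live on the output grid in world mm, with pull-back
resampling: output voxel at world $x$ samples the input at $x + d(x)$.
That convention is stated nowhere upstream, so it is stated here.
The three evaluation metrics are the Jacobian determinant
$\det(I + \partial d/\partial x)$ (central differences in mm, one-sided
at borders; exact for quadratic fields), per-label Dice over voxel
counts (grids are shared by precondition), and fiducial misregistration
(Euclidean, reported as mean ± SD and max, matching the field's
reporting shape). Trilinear warping is exact on affine intensity ramps,
which the tests exploit as a closed-form oracle.

## The iso-to-allocortical axis

The axis is the edge-weighted geodesic distance from a set of bridgehead
vertices (where isocortical and allocortical surface constructions
meet); it is 1-Lipschitz along edges by construction. Volumetrisation
fills every voxel whose centre lies between pial and white with the axis
value of its nearest surface vertex. Membership is decided against a
barycentric supersampling of the sheet (samples spaced about half a
voxel), projecting the voxel centre onto the local pial–white segment:
longitudinal fraction in [0, 1] and lateral offset within 0.75 of the
sample spacing. The supersampling bounds the lateral quantisation error
by the voxel size, which is what lets the slab fixture conserve ribbon
volume to a few percent.

Axis-binned connectivity uses equal-width bins over the axis range
(right-closed last bin; equal-count binning would also have been
defensible — equal-width was chosen for determinism and simplicity),
default 100 bins against 1,000 isocortical parcels. Empty bins are
dropped with their indices recorded; zero-variance timeseries give `NA`
rsFC. The per-parcel trend is the Pearson correlation of rsFC against
bin position. Because correlation saturates, a strongly coupled parcel's
rsFC flattens near 1 across bins and the *linear* trend statistic
degrades — the planted-recovery studies therefore couple weakly
(slope 0.3 against unit voxel noise), keeping bin-level rsFC in the
regime where a linear coupling gradient appears as a linear rsFC trend.
With a single coupled parcel, uncoupled parcels also inherit a spurious
rsFC *shape* through finite-sample correlations between parcel
timeseries (trend r is scale-free); null-trend calibration is therefore
checked on the all-zero-coupling simulation, where 95% of parcels fall
within $\pm 2/\sqrt{n_\mathrm{bins}}$.

## Synthetic fixtures: what they emulate, and what they do not

`make_folded_sheet()` builds a sinusoidally folded pial sheet
($z = A\sin(fx)$) with the white surface offset along the local normal —
vertex-correspondent, one shared face table, and a self-intersection
guard (`thickness × A f² < 1`). The default (amplitude 2 mm, frequency
0.4 /mm, thickness 2 mm, 0.5 mm spacing) folds strongly enough that pial
and white areas differ by tens of percent, which is what the
equivolumetric-vs-equidistant comparisons need.

`make_laminar_volume()` plants a six-layer density model. Each voxel's
depth is converted to a *volume* fraction through the inverse
equivolumetric map using the sheet's own vertex areas, so the planted
laminae are equivolumetric by construction and layer volume fractions
are recoverable by voxel counting (the tests check them to 2 percentage
points). The default boundaries (0.1, 0.25, 0.4, 0.5, 0.75, 1) and
densities (30, 90, 60, 120, 70, 50) give a thin high-density band at
fractions 0.4–0.5 and a secondary superficial band — a "layer IV" and
"layer II" — so the fixture's characteristic profile has exactly two
peaks. The default noise SD is 0: the default spec *is* the
deterministic laminar model, because under strict plateau-aware peak
counting any additive noise manufactures extra strict maxima on the
piecewise-flat plateaus, and the two-peak property is the fixture's
defining feature. Noise is an explicit dial; the recovery and
autocorrelation studies use SD 2 (a tenth of the inter-layer density
steps) as their stated condition.

What the fixtures deliberately do not emulate: histology texture within
layers, blood vessels, staining artefacts, scanner noise spectra, or
curved (non-prismatic) cortical columns. Passing tests show the
machinery is correct on geometry it fully controls; they do not certify
behaviour on artefact-ridden real volumes.

## Problem sizes and numerics

The test and acceptance workloads use a 30 × 10-vertex folded sheet
(300 columns) at 0.1 mm voxels (~470k voxels), 50 surfaces, 200 planted
parcels for the gradient study, and V = 2000, T = 300 for the BOLD
study — sizes chosen so every study runs in seconds while leaving the
planted effects far from marginal. Full geodesic distance matrices are
computed dense (meshes here are ≤ a few thousand vertices); the
smoothing truncation is applied after the fact. Degenerate inputs are
handled as flags rather than errors wherever a partial result is
meaningful: out-of-volume samples (mask bit), out-of-grid fiducials
(per-point flag), disconnected components (infinite distance), empty
ribbon (warning plus empty volume), zero-thickness columns (equidistant
fallback with a warning), zero residual variance and zero-sum profiles
(`NA`).

## Known limitations

- Graph geodesics overestimate true surface distance on coarse meshes;
  all distance-based quantities (smoothing kernels, the axis) inherit
  that bias consistently.
- The ribbon is built from per-column prisms; strongly oblique columns
  in thick, tightly folded cortex could be assigned to a neighbouring
  column near fundi.
- `surface_resample()` assumes the two spheres share a registration
  frame (approximately common centre); it does not itself register.
- GIFTI support covers pointset/triangle/func/label arrays with ASCII
  and (gzipped) base64 encodings — the subset the toolkit reads and
  writes — not external-file data arrays or CIFTI.
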