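---
title: "Models and methods behind seedmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`seedmech` packages the computational chain of a shape-driven-stress
analysis of seed morphogenesis: a mechanical model of the pressurized seed
coat, curvature and orientation statistics on cellularized surfaces,
nematic-tensor fibril quantification in 2D images, and growth morphometry,
together with synthetic-data generators that provide ground truth for every
analyzer. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic tests do and do not establish
about real data.

## The pressurized-shell model

The seed coat is idealized as a thin closed elastic membrane of uniform
thickness *t* (µm) under uniform internal pressure *p* (MPa) — turgor of
the enclosed endosperm. Bending stiffness is neglected: for a thin
pressurized convex shell the in-plane (membrane) stress state is
*statically determinate* — fixed by equilibrium on the current geometry
alone, a generalized Laplace law — so the elastic constants control the
displacement magnitude, not the stress pattern. The solver verifies this
numerically: stresses are invariant to Young's modulus exactly (linear
solve) and to the Poisson ratio to within discretization error.

Discretization uses constant-strain triangles in plane stress, assembled
over the closed icosphere-derived mesh, with the pressure applied as
consistent nodal loads along face normals. Rigid-body motion is removed by
constraining six degrees of freedom on three mutually distant vertices
(one fixed, one free only along the joining line, one free only in the
plane of the three); on a strictly convex triangulated surface the
remaining stiffness is positive definite (convex triangulated polyhedra
are infinitesimally rigid), and the test suite checks that the solution is
unchanged when a different vertex triple is constrained.

Two configurations are exposed:

* `configuration = "reference"` — a small-strain solve on the given shape.
  This is the mode validated against closed forms: σ = pR/(2t) on the
  sphere, and the spheroid membrane-theory formulas
  σ_m = pR₂/(2t), σ_h = (pR₂/t)(1 − R₂/(2R₁)) implemented in
  `spheroidStressOracle` (R₁ = a²b²q³, R₂ = b²q,
  q = √(sin²λ/a² + cos²λ/b²); at the poles R₁ = R₂ = b²/a).
* `configuration = "inflated"` — the model-prediction mode. The shell is
  first inflated to its finite-strain equilibrium (total-Lagrangian
  St.Venant–Kirchhoff membrane, follower pressure, Newton iteration under
  a pressure ramp with residual backtracking), and the reported field is
  the statically determinate stress carried by the inflated shape.

The distinction matters on the flattened faces of the seed shape. On the
*fixed* triaxial ellipsoid the converged membrane solution is nearly
isotropic at the flat-face center, with the major axis marginally along
the long axis — we verified this is not a discretization artifact (stable
across refinements 2–5 and Poisson ratios 0–0.45, and consistent with the
spheroid oracles in both revolution limits). An *inflated* shell behaves
differently: inflation bulges the shallow flat faces, and the stress that
equilibrates pressure on the bulged shape is circumferential ("hoops"
around the long axis) over the whole non-tip surface, which is the
configuration in which stress and curvature axes correlate. Since the
biological object is an inflated shell — the observed shape is the loaded
configuration produced by turgor — the pipeline and the model-prediction
checks use the inflated mode; the reference mode remains the oracle-testing
ground because its closed forms are exact.

Default material parameters are E = 100 MPa, ν = 0.3, t = 1 µm,
p = 0.2 MPa. These are placeholders in the sense that every reported
comparison is a ratio, a direction or an anisotropy, which the statics
makes insensitive to E and ν; p/(tE) does set the inflation magnitude in
the inflated mode (≈ 15% strain scale with the defaults, enough to round
the cross-section without changing the qualitative pattern).

Stress anisotropy is (σ₁ − σ₂)/(σ₁ + σ₂) ∈ [0, 1]; per-cell tensors are
area-weighted means of per-face tensors, eigen-decomposed after projection
onto the cell tangent plane.

## Surface curvature and the θ statistic

Per-cell curvature is estimated by least-squares fitting a quadric height
function z = z₀ + Dx + Ey + (Ax² + 2Bxy + Cy²)/2 in the cell's tangent
frame to all mesh vertices within a fixed surface distance of the cell
centroid, and eigen-decomposing the shape operator of the fit. Distances
are shortest paths on the edge graph (a geodesic surrogate; a Euclidean
option exists behind a flag). The intercept z₀ is included because cell
centroids do not lie exactly on the surface; forcing the fit through the
origin biases the curvatures. Curvatures are positive for a convex surface
with outward normals (a sphere has κ = +1/R), and curvature anisotropy is
(κ_max − κ_min)/(|κ_max| + |κ_min|).

The neighborhood radius is the cell-scale smoothing window: 30 µm is the
default used for 2-days-post-anthesis (2DPA) seeds, 60 µm is appropriate
at 5 DPA when cells have enlarged — roughly the distance from a cell
center to the far edge of its direct neighbors. An adaptive per-cell
radius would be a natural extension; the package implements the fixed
radius only. The estimator requires the radius to exceed twice the mean
edge length and at least six neighborhood vertices per cell.

The CMT-to-curvature statistic is the axial angle
θ = cos⁻¹(|u·v|) ∈ [0°, 90°] between unit tangent axes — symmetric,
sign-free, and invariant under rigid rotation of mesh and fields (tested
to 10⁻⁶). Distributions are summarized with 18 bins of 5° and a median
(robust to the long tail a minority of disordered cells produces); the
mean and the fraction below 30° are also reported.

## Fibril quantification

`fibrilTensor` implements the image-gradient nematic tensor: Gaussian
pre-smoothing (σ = 1 px default, recorded in the output), per-pixel
gradients, fibril axis = gradient rotated 90°, and the weighted mean of
u uᵀ − I/2 over the ROI with squared-gradient-norm weights (unit weights
available for sensitivity analysis). The orientation is the principal
eigenvector angle; the score is the eigenvalue difference of the
weight-normalized tensor, clamped to [0, 1].

One numerical choice deserves note: gradients use the Scharr 3×3 stencil
rather than the plain two-point central difference. The plain stencil's
direction response is anisotropic near the Nyquist frequency, which biases
orientation estimates toward the diagonals by up to ~1° on band-limited
textures — enough to break a ±1° recovery contract. The Scharr weights are
the standard optimization of exactly this error; with them a 40° rotation
of a texture shifts the measured orientation by 40.2° and the score by
< 0.01. Organization scores remain preprocessing- and projection-dependent
in general (measurements from z-sections, 2D projections and 2.5D meshes
are not interchangeable), which is why the smoothing and weighting
settings are carried in every output row and scores should only be
compared within one analysis route.

## Morphometry

Seed silhouettes are binarized with the Huang minimum-fuzziness threshold
(computed on a 256-bin histogram) and touching seeds are separated by a
watershed on the distance transform of the mask. Objects under 100 px²
are discarded; objects with solidity < 0.8 are kept but flagged (the
interactive practice of manually removing bad segmentations is replaced
by this heuristic). A guard treats images whose two intensity classes are
separated by less than three pooled within-class standard deviations as
having no foreground, so pure background noise is not segmented into
speckle.

Shape measurement offers the two conventions that coexist in practice:
`mode = "ellipse"` (major/minor axes of the second-moment-matched
ellipse, the mature-seed "Fit Ellipse" convention) and `mode = "axes"`
(longest principal-axis chord through the centroid and the perpendicular
extent through its midpoint, the automated proxy for the manually drawn
pedicel-to-tip line of developing seeds). Both return aspect ratio L/W
and are rotation- and scale-invariant within 1%.

Organ-scale growth series apply the derivative and SD-propagation
formulas exactly: rate(n→n+1) = (meanₙ₊₁ − meanₙ)/meanₙ and
sd = √((sdₙ₊₁/meanₙ₊₁)² + (sdₙ/meanₙ)²), for area (growth rate) and for
aspect ratio (growth anisotropy — the printed derivative formula is shown
for area; its application to aspect ratio follows the way the growth
anisotropy series is used alongside it). Per-cell growth maps fit the
best 2×2 linear map between matched boundary points of parent and
offspring cells after projection to the cell tangent plane; growth
anisotropy is λ₁/λ₂ ≥ 1 (isotropic = 1) with the λ₁ direction as the
main axis, and areal growth is Σ offspring areas / parent area − 1.
Dimension-change statistics summarize per-cell percent changes by the
per-seed *median*, deliberately robust to the occasional segmentation
outlier.

## Synthetic data: what it emulates, and what it does not

Generators provide every input with known ground truth:

* **Meshes** — icosahedral subdivision projected radially to the
  ellipsoid (near-uniform triangles, no pole artifacts); the default
  "2DPA seed" is (a, b, c) = (170, 100, 85) µm, i.e. aspect ratio 1.7
  with thickness 15% below width; absolute scale cancels from every
  direction/anisotropy output. Ovule-like shapes (aspect ratio ≈ 0.8) can
  be generated by reordering axes but are not validated against any
  measurement. A planar sheet (`makePlanarMesh`) stands in for the
  near-planar flat face in cell-growth tests, where an in-plane affine
  stretch is recovered exactly.
* **Tessellations** — random surface seeds with Lloyd-style centroidal
  relaxation and nearest-seed face assignment, repaired to face-connected
  cells. This emulates the sizes and adjacency of segmented epidermal
  cells, not their lineage-correlated shapes or oriented divisions.
* **Fibril textures** — white noise filtered with an elongated Gaussian
  kernel along the ground-truth axis (σ_along = 12 px, σ_across = 2.5 px,
  kept away from Nyquist so gradients are well resolved), band-passed,
  and blended with isotropic noise with weight 1 − anisotropy. Realistic
  in second-order statistics; not a model of microtubule bundling,
  crossovers or confocal optics.
* **CMT fields** — axial draws via the standard device of a von Mises
  distribution on doubled angles (sampled with the Best–Fisher rejection
  scheme), centered on the maximum-curvature axis rotated by a chosen
  offset; κ = 0 gives uniform axes (mean θ = 45°), large κ tight
  alignment. The organization score attached is the doubled-angle mean
  resultant length I₁(κ)/I₀(κ).
* **Silhouettes** — rasterized ellipses over a noisy background with
  smooth radial boundary noise restricted to harmonics ≥ 3: the h = 2
  harmonic is the elliptic-distortion mode and would silently change the
  recorded ground-truth axes.
* **Growth observations** — lognormal scatter about daily means,
  parameterized so the arithmetic mean is exact and the coefficient of
  variation equals the requested value.

Passing the loop-back suite therefore shows that each analyzer recovers
the parameters of data generated under its own assumptions at realistic
noise levels — a necessary condition, not a validation on microscopy
data. Image-derived inputs from real experiments (2.5D projections,
manual segmentations) have artifacts none of these generators emulate.

## Reproducibility and problem sizes

All stochastic functions take a mandatory integer seed and restore the
caller's RNG state; pipeline stages derive their seeds deterministically
from a root seed and the stage name, so adding a stage never perturbs
earlier draws, and rerunning a configuration reproduces its CSV outputs
byte for byte. The default problem sizes — refinement-4 meshes (5120
faces), 300-cell tessellations, 256²–512² textures — were chosen so the
oracle tolerances (2% sphere stress, 5% spheroid ratio and curvature,
±1° fibril orientation) hold with margin while a full validation run
completes in about a minute on one CPU.

## Known limitations

* The shell model is static and purely membrane: no bending, wrinkling
  (flank minor stresses sit near zero, so compressive instabilities are
  nearby in parameter space), growth mechanics, wall-layer heterogeneity
  or contact.
* The inflated configuration takes the stated ellipsoid as the reference
  shape; calibrating a reference that inflates *to* a prescribed shape is
  not implemented.
* Curvature neighborhoods use a fixed radius; adaptive per-cell radii are
  not implemented.
* The fibril module supports the 2D-image route only; extracting CMT
  signal from image stacks is out of scope.
* Cell-growth recovery is exact on planar patches; on curved surfaces the
  reported quantities are the in-plane components of the same affine map,
  and the generator applies divisions as median splits across the cell's
  long axis rather than modelling oriented division rules.
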