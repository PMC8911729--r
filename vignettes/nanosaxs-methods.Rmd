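---
title: "Methods: scanning-SAXS nanomechanical imaging with nanosaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning-SAXS nanomechanical imaging with nanosaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nanosaxs)
```

## The measurement

Collagenous tissue scanned with a microfocus X-ray beam produces, at
each scan position, a 2D small-angle scattering (SAXS) pattern. Two
families of features carry the nanostructural signal:

* **Meridional collagen orders.** The ~65 nm axial staggering
  (D-period) of tropocollagen molecules produces Bragg peaks at
  $q_n = n \cdot 2\pi/D$. The 5th order is used for quantification
  because the diffuse background is near-linear in its window
  (0.40–0.52 nm⁻¹), whereas the stronger 3rd order sits on steeply
  curved background. From the fitted center, $D = 10\pi/q_{05}$.
* **An interfibrillar component (IFC).** A broad equatorial peak
  family from a ~88–100 nm lateral spacing between fibrils and an
  interfibrillar phase; the 2nd order is fit and
  $D_\mathrm{IFC} = 4\pi/q_2$. The 1st order is partly shadowed by the
  beamstop.

Changes in the D-period between load states give the **fibril strain**
$\varepsilon_F = \Delta D / D$, to be compared with the macroscopic
tissue strain $\varepsilon_T$; the azimuthal intensity $I(\chi)$ gives
the mean fibril angle $\chi_0$ (180°-periodic) and the orientation
spread $w_\chi$.

## Reduction geometry

`detector_geometry()` holds distance, pixel size, beam center, energy
(wavelength $\lambda = 1.23984/E$ nm·keV) and frame shape. Full
$2\theta = \arctan(r/L)$, $q = (4\pi/\lambda)\sin\theta$ geometry is
used; the small-angle approximation saves nothing here and would add an
avoidable approximation. The azimuth convention is **counterclockwise
from the detector +x (column) axis, degrees in [0, 360)**, chosen for
`atan2` compatibility; it is applied consistently in reduction, fitting
and simulation.

Binning uses the **mean of pixel counts per bin** (not the sum), so bins
with different pixel populations are comparable, and each populated bin
is labelled with the **mean q (or χ) of its contributing pixels** rather
than the geometric bin center. The latter matters at desk-scale frame
sizes, where sub-bin structure in the available pixel radii otherwise
biases fitted peak centers by a detectable fraction of a bin. Masked
pixels (beamstop, dead zones) are excluded, never imputed. Empty bins
are flagged, never interpolated.

`refine_distance()` recovers the sample-to-detector distance from
calibrant ring radii (e.g. silver behenate) by least squares; geometry
is otherwise taken from a config file, not re-derived.

## Peak models

All radial peaks use a Gaussian plus diffuse background, fit by
Levenberg–Marquardt. Two background families are implemented:
**exponential decay** (the default) and a **linear slope**; the choice
is a function argument and is recorded in the fit object. The
exponential is internally parameterized by its value at the window start
— the naive amplitude/decay pair is degenerate along a ridge and stalls
the optimizer. Initialisation is deterministic (argmax of the
endpoint-detrended window; width from its half-maximum span) with a
small fixed grid of fallback starts, so no fit depends on a random seed.
Widths are reported as the Gaussian **sigma**; `fit_fwhm()` converts.
A fitted center pinned to a window edge is reported as non-converged;
non-convergence always yields a flagged result, never an error.
Plausibility bands (D in 60–72 nm, D_IFC in 50–200 nm) flag values
without rejecting them.

The azimuthal model is a baseline plus **three Gaussians**: principal
peaks at $\chi_0$ and $\chi_0 + 180°$ with a shared width and free
amplitudes (tilt of the fibril population relative to the Ewald sphere
makes unequal arc intensities physical), plus one wrap replicate 360°
from the principal peak nearest a domain edge, cloning its amplitude
and width. The replicate is what makes fits invariant under circular
shifts of the 0°→360° origin. Profiles whose fitted amplitude is below
3× the residual noise are flagged isotropic; the threshold is an
argument.

`order_ratios()` fits each requested meridional order in its own window
(half-width 0.35 of the fundamental spacing) with the same model family
and reports background-corrected areas relative to the 5th order.

## Maps and thresholding

`assemble_map()` places per-point fit columns on the scan grid
(row-major raster by default), masking missing or non-converged points;
`threshold_mask()` reproduces the sparse representation in which
spacings are shown only where the corresponding peak intensity exceeds
a minimum — D-values from points with negligible scattering are
artefactual. `render_grayscale()` scales linearly into 8- or 16-bit
gray; the default range is the 1st–99th percentile of valid cells so a
few hot cells do not flatten the contrast that DIC needs.

## The DIC engine

`dic_correlate()` implements subset DIC with the processing scheme used
on collagen peak-intensity maps: **25×25 px subsets, 3 px step** as
defaults, **round weighted windows** and a **6th-order spline** for
gray-level interpolation, and a **7×7-subset strain window**
(`dic_strain()` fits planes to u and v over that neighbourhood; the
plane gradients are the strains). Choices the original processing
chain does not publish were made as follows and are configurable:

* **Similarity criterion: ZNCC** (zero-normalized cross-correlation) —
  invariant to intensity offset and gain, which differ between load
  steps.
* **Round window**: circular support of radius (subset−1)/2 with a
  raised-cosine radial taper starting at half the radius.
* **Subpixel optimizer**: inverse-compositional Gauss–Newton over a
  translation + affine shape function; convergence at update norm
  < 10⁻⁴ px or 50 iterations; deterministic.
* **Interpolation**: cardinal B-spline of degree 6 (recursive
  prefilter + separable evaluation); boundaries use whole-sample mirror
  symmetry, so subsets near borders remain evaluable.
* **Validity**: zero-variance subsets, non-converged iterations,
  correlation below the threshold, or subsets warped off the image are
  invalid; masked map cells get zero subset weight, and subsets with
  more than half their window weight masked are invalid.
* **Large deformations**: an optional pyramid pre-pass (2× downsampled
  whole-image correlation) seeds the integer search, since a 20%
  stretch on a small map can exceed a naive search radius.

`dic_displace_points()` interpolates the field bilinearly to arbitrary
points. Points outside the convex hull of valid subset centers are
extrapolated with a global affine fit of the field and flagged;
low-order extrapolation of boundary displacements is standard DIC
practice and is exact for affine tissue motions.

## Matching scan points and nanomechanics

`match_points()` displaces each reference scan point through the DIC
field and **snaps to the nearest deformed scan point**. Snapping, not
interpolation: D and $\chi_0$ are per-voxel fitted quantities, and
interpolating them would mix distinct tissue volumes. The snap distance
is reported so users can filter; pairs snapping farther than one scan
step are flagged.

`fibril_strain()` is $(D_\mathrm{def}-D_\mathrm{ref})/D_\mathrm{ref}$;
`reorientation()` works on the 180°-periodic circle with shortest arcs,
positive values meaning rotation toward the loading axis (default 90°,
vertical tension). `distribution_summary()` uses a Gaussian-kernel KDE
with Silverman's rule-of-thumb bandwidth (no bandwidth is prescribed by
the application; Silverman is the conventional default) on a 512-point
grid; the mode is the grid argmax.

## The synthetic generator

`simulate_frame()` emulates a photon-counting (Pilatus-like) detector
frame: exponential diffuse background, collagen orders n = 1..6 as
Gaussian rings with angular lobes at $\chi_0$ and $\chi_0+180°$, order
amplitudes proportional to $|c_n|^2$ of a two-level axial step density
($c_n = \sin(\pi n f)/(\pi n)$, f the gap fraction — so a half/half
gap/overlap split extinguishes even orders), and an IFC ring family
(orders m = 1, 2; lobes rotated 90° from $\chi_0$; the m = 1 ring
partly under the beamstop disk). Noise is Poisson only — appropriate
for a photon-counting detector, which has no read noise. Identical
seeds give bit-identical frames.

Desk-scale geometry (`desk_geometry()`) keeps the q range of the full
1475×1679 px / 172 µm detector at reduced resolution (512² by default)
by rescaling the pixel size. At 256², one pixel spans ≈ 0.015 nm⁻¹ of
q at the 5th order, so simulated scans at that scale use a collagen
radial width of 0.012 nm⁻¹ — an instrumentally broadened peak that
stays resolvable — and a 5th-order window of 0.43–0.54 nm⁻¹ that
excludes bleed from the (equally broadened) 4th order. These are
properties of the reduced simulation scale, not of the fitting method;
at full detector scale the default width (0.004 nm⁻¹) and window
(0.40–0.52 nm⁻¹) apply.

`tissue_model()` defines smooth log-normal textures for collagen and
IFC intensity (correlation length 4 scan steps, log-sd 0.8 — strong
microspatial heterogeneity with voids, which is exactly the contrast
DIC tracks), an additive D-period texture (sd 0.05 nm, matching a
~0.2 nm point-to-point spread), and an orientation texture (sd 25°
about the mean angle). `simulate_deformed_scan()` samples the same
continuous tissue through a bijective warp (default: 20% uniaxial
stretch about the bottom row, the tensile geometry with the reference
edge held), imposing a uniform fibril strain (default 0.0015) and a
fractional reorientation toward the loading axis (default 0.5), and
returns the exact point-correspondence oracle.

What the generator does **not** emulate: cylinder form factors and
Ewald-sphere tilt effects (angular lobe amplitudes are free parameters
instead), detector flat-field and polarization corrections (the
analysis uses relative intensities only), beam smearing, and sample
absorption. Passing tests therefore demonstrate correctness of the
reduction/fitting/DIC chain under the stated intensity model, not
robustness to every instrumental artefact of real beamline data.

## Problem sizes and tolerances

The test-suite simulations are sized for a desk run: parameter-recovery
grids use 220-bin profiles with a few replicates per truth cell; DIC
checks use 72–110 px speckle images with 17–25 px subsets; the
end-to-end load step uses a 24×24 scan of 256×256 px frames (and its
deformed 29×24 counterpart) with 9 px subsets at 1 px step on the
native-resolution maps. Numerical tolerances follow the quantity:
spline interpolation reproduces pixel values to ~10⁻⁹, DIC
zero-displacement bias is below 10⁻³ px, and D-period recovery is
assessed against a 0.02 nm median-error bound.

## Known limitations

* The IFC 2nd-order default window (0.115–0.15 nm⁻¹) is narrower than
  the peak it fits (sigma ≈ 0.016 nm⁻¹), which biases the fitted
  spacing by a few nm on synthetic data; pass a wider window when the
  surrounding background allows it.
* DIC equivalence with the commercial processing chain is claimed at
  the level of recovered synthetic warps, not bit-exact displacement
  fields — the commercial criterion, taper and outlier handling are
  proprietary.
* Strain from `dic_strain()` is the gradient of a plane fit over the
  strain window: real strain gradients shorter than the window are
  smoothed, and boundary cells with truncated windows carry an O(h)
  bias on curved fields.
* `fit_azimuthal()` assumes exactly one (180°-paired) orientation
  population; crossed-fiber regions will fit poorly and should be
  caught via `residual_norm` and the isotropy flag.
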