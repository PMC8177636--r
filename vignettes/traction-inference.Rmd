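---
title: "Inferring nuclear traction forces from outline deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nuclear traction forces from outline deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuctraction)
```

## The inverse problem

When a cell migrates through a constriction narrower than its nucleus, the
nucleus must deform, and the forces doing the deforming are of direct
biological interest — yet they cannot be measured. What *can* be measured
routinely is the nuclear outline at successive time points, from
fluorescence images of the stained nucleus. `nuctraction` solves the
resulting inverse problem: given two successive closed outlines of an
elastically deforming nucleus, reconstruct the deformation field between
them and compute the surface traction \(t_i = \sigma_{ij} n_j\) (force per
unit area, in Pa) that must have produced it.

The catch is that two outlines do not determine a deformation field: any
boundary correspondence is geometrically admissible. The package adopts the
standard physical closure — among all order-preserving correspondences, the
physical one minimises the elastic free energy of the deformation — and
searches for that minimiser by Metropolis simulated annealing.

## Mechanical models

Two single-parameter-family models bracket the unknown interior rheology of
the nucleus.

**Homogeneous incompressible elastic solid.** The whole nucleus is an
elastic continuum with Young's modulus \(E\) (default 5000 Pa) and Poisson
ratio \(\nu = 0.5\). Hooke's law
\[
\sigma_{ij} = \frac{E}{1+\nu}\Bigl(\epsilon_{ij} +
  \frac{\nu}{1-2\nu}\,\epsilon_{kk}\,\delta_{ij}\Bigr)
\]
is implemented with an *exact* incompressible branch: at \(\nu = 0.5\) the
strain trace vanishes by construction and the law reduces to
\(\sigma_{ij} = \tfrac{2E}{3}\epsilon_{ij}\); the \((1-2\nu)^{-1}\) factor
is never evaluated and no \(\nu = 0.4999\) regularisation is used. The
interior displacement is extrapolated linearly along radial spokes from the
boundary values to zero at the centre of mass (the polygon centroid), which
makes the displacement field positively homogeneous in the radius; a direct
consequence — and a useful verification — is that all stress components are
constant along each spoke.

Strains are evaluated on a polar mesh (default 20 radial rings by the
boundary point count) by finite differences: central differences in the
angular direction (periodic), second-order one-sided stencils at the inner
and boundary rings, mapped to Cartesian derivatives through the mesh
Jacobian. For displacement fields that are affine in space these stencils
are *exact*, which the tests exploit: rigid rotations produce strains at
machine precision rather than at truncation accuracy.

The out-of-plane direction is closed by incompressibility,
\(\epsilon_{zz} = -(\epsilon_{xx} + \epsilon_{yy})\), with
\(\epsilon_{xz} = \epsilon_{yz} = 0\) on the imaging mid-plane; the outline
normal is perpendicular to \(z\), so \(\sigma_{zz}\) never enters the
surface traction.

**Thin elastic shell.** Only the nuclear lamina — a \(\sim\)100 nm
intermediate-filament shell — resists deformation; the interior is free.
Displacements are rotated into the surface basis \((\hat n, \hat s_1, \hat
s_2)\) (outward normal, in-plane tangent, out-of-plane tangent) by the
rotation \(R_\phi\), where \(\phi\) is the angle between \(\hat n\) and
\(\hat x\). On a curved outline the derivative of the basis vectors couples
displacement to strain through the single nonzero curvature component
\(C \equiv C_{s_1 s_1}\) (the out-of-plane curvature vanishes because the
nucleus fills the channel in \(z\)):
\[
D_s = \partial_1 u_{s_1} + C\,u_n, \qquad
D_n = \partial_1 u_n - C\,u_{s_1}.
\]
The tangential stretch is \(\epsilon_{s_1 s_1} = D_s + q\,(D_s^2 + D_n^2)\)
with \(q\) the quadratic-term coefficient of the active strain convention;
the element tilt enters as the shear \(\epsilon_{n s_1} = D_n/2\) (the
normal derivative of \(u_{s_1}\) is unconstrained by the resistance-free
interior and is taken as zero); \(\epsilon_{s_2 s_2} = -\epsilon_{s_1 s_1}\)
closes the tensor trace-free, consistent with constant shell thickness and
constant enclosed volume; \(\epsilon_{nn} = 0\) by the thin-shell
(Love–Kirchhoff) assumptions. Because \(\epsilon_{nn} = 0\) and the
material is incompressible, \(\sigma_{nn} = 0\) and the traction
\(t = \sigma \hat n = \sigma_{n s_1} \hat s_1\) is *exactly tangential* —
the shell model's signature, promoted to a hard invariant in the test
suite. A design note: taking the thin-shell statement "only tangential
strains are nonzero" fully literally would zero the shear as well and make
the traction vanish identically for every deformation; the shear term is
what reconciles the thin-shell kinematics with a nonzero tangential
traction, and it is isolated in one function should a different closure be
preferred.

Tractions are reported in Pa at the mid-surface; the shell thickness `h`
enters only the total-energy integral \(\int f\,h\,ds_1\,H(x)\), with
\(H(x)\) the local channel height.

**Strain conventions.** The strain tensor is
\[
\epsilon_{ij} = \tfrac12\bigl(\partial_i u_j + \partial_j u_i\bigr)
 + q\,\partial_i u_k \partial_j u_k ,
\]
with `strain_convention = "as-printed"` using \(q = 1/4\) and
`"green-lagrange"` the standard finite-strain \(q = 1/2\). The first is the
form this line of work prints; it is *not* invariant under rigid rotations,
which is why both are exposed behind one flag (`elastic_params()`) and the
rotation-invariance tests run under the second. Neither is chosen silently.

## From images to outlines

`otsu_threshold()` minimises the intra-class intensity variance over the
histogram (exhaustively, ties broken to the lowest threshold — fully
deterministic), and `extract_contour()` binarises, keeps the largest
8-connected component, fills interior holes and traces the outer boundary.
Tracing follows pixel *edges* (crack following) rather than pixel centres:
the traced polygon of a \(w \times h\) pixel block then has perimeter
exactly \(2(w+h)\) px and area exactly the pixel count, which keeps
area-based volume estimates unbiased at the one-pixel level. The traced
path is resampled to points spaced one pixel apart and converted to µm
(default 0.215 µm/px) with the y axis flipped so y increases upward.
Optional smoothing (truncation to a configurable number of Fourier
harmonics) replaces the interactive spline-fitting step of manual
workflows; the default applies no smoothing, because any fixed smoothing
constant would be an unverifiable guess.

Volumes are estimated as mid-plane area × channel height (4.7 µm in the
channel, 3.4 µm in the constriction by default), splitting outlines that
span the constriction entrance or exit at those boundaries
(`estimate_volume()`, `volume_report()`).

## Averaging and alignment

Outlines of many nuclei at a common migration stage are averaged by casting
radial spokes at equal angles from each outline's centroid and averaging
the spoke-intersection coordinates (`average_contours()`). Star-shapedness
about the centroid is *enforced*, not assumed — the spoke construction is
undefined otherwise, and violations name the offending input and angle.

Because the nucleus translates as it deforms, an initial/target pair must
be registered before a deformation field is meaningful. Neither
centroid-on-centroid nor rear-on-rear registration is right in general, so
`align_pair()` interpolates: with rear (minimum-x) and front (maximum-x)
displacements \(\Delta r, \Delta f\) between the raw frames, the applied x
shift is
\[
s = w\,\Delta f + (1 - w)\,\Delta r, \qquad
w = \frac{|\Delta r|}{|\Delta r| + |\Delta f|},
\]
so the end that moved less anchors the registration; a pure translation is
removed exactly and a symmetric dilation reduces to centroid alignment.
The weight rule lives in one small function (`alignment_shift`) so that a
different proportionality policy is a one-line swap. Rotational
registration is deliberately absent: channel geometry constrains motion to
the x axis.

## The annealing search

`anneal()` starts from the equal-angle correspondence (both outlines
remeshed about the origin of the aligned frame to a common point count) and
repeatedly perturbs the mapped position of one random point a fraction
(default 1/10) of the way towards one of its two neighbours. Downhill moves
are always accepted; uphill moves with probability \(\exp(-\Delta E/T)\).
The temperature starts at a value calibrated so that about 20% of proposals
from the starting state would be accepted and decays geometrically (default
0.95 per sweep of \(n\) proposals). The best-so-far mapping is tracked and
returned; its energy trace is non-increasing by construction. Termination
is stall-based: a configurable number of sweeps with relative best-energy
improvement below \(10^{-6}\).

Three details deserve attention:

* **Order guard.** Proposals that would break the anticlockwise order of
  the mapped points (the multi-valued-surface failure mode) are rejected
  before any energy evaluation.
* **Degenerate calibration.** If more than the target fraction of initial
  proposals is already downhill, no finite temperature is cold enough to
  reach the target overall acceptance; calibration then warns and returns
  an effectively zero temperature, degrading the search to greedy descent.
  This is the faithful reading of the 20%-overall-acceptance rule; pass an
  explicit `temperature` in `anneal_config()` to keep genuine annealing in
  that regime.
* **Chord erosion and `reproject`.** Moves slide mapped points along
  straight chords between their neighbours, so on a convex outline every
  accepted move pulls the point slightly *inside* the target outline, and
  long runs systematically shrink the mapped polygon (and with it the
  apparent deformation energy). `anneal_config(reproject = TRUE)` snaps
  each proposal back onto the target outline. The default is off, matching
  the plain description of the move rule.

The energy compared is the model's *total* energy (density integrated over
the reference mesh volume, or over the shell), so `T` carries energy units
with Boltzmann's constant absorbed. The solid model's inner-loop evaluator
exploits the spoke-constancy of the stress to reduce the volume integral to
boundary quantities with precomputed weights; it is verified against the
full mesh integral to \(10^{-15}\) relative in the tests.

## What the synthetic generator does and does not establish

`make_shape()` produces circles, ellipses, stadiums and three
channel-stage shapes (channel-filling body; body with a tapered tongue
protruding into the constriction; long narrow shape inside) whose areas
reproduce the measured mean nuclear volumes (242 µm³ outside, 231 µm³
inside the constriction) divided by the respective channel heights, in the
default 7 × 4.7 µm channel with a 2 × 3.4 µm, 20 µm long constriction and
45° entrance tapers. `make_deformation_pair()` applies exact analytic maps
(translation, dilation, area-preserving affine, area-preserving
constriction squeeze) and stores the per-point ground truth.
`rasterize_contour()` closes the loop to the segmentation stage with
seeded, reproducible noise.

A green test on these fixtures establishes that the machinery — geometry,
elasticity, search, I/O — does what its contracts say on shapes of the
right scale and class. It does *not* establish that real average nuclear
outlines are star-shaped about their centroids (enforced, and real
near-constriction shapes can violate it), nor anything about imaging
physics: no point-spread function, no photobleaching, no fluorophore
statistics are emulated.

## A known limitation: the energy minimiser is not the generating map

One natural validation — deform a circle by an area-preserving affine map
into an ellipse, run the solid-model annealer, and ask whether the
recovered per-point deformation matches the generating map to a few
per cent — fails, and instructively so. The minimum-free-energy boundary
correspondence between the circle and the ellipse is *not* the affine
correspondence: the affine map is not even a local minimum of the
solid-model energy (single-point tangential perturbations lower it), and
the true minimiser redistributes points tangentially, sitting roughly a
quarter of the mean deformation magnitude away from the affine ground
truth. This was cross-checked with an independent P1 triangle
finite-element discretisation of the same energy, which agrees with the
package's finite-difference energy on both the affine and the annealed
correspondences; it is a property of the model, not a discretisation
artefact. (Its physical root: with a free tangential boundary condition,
uniform strain is not the cheapest way to realise a given shape change.)
The corresponding acceptance test is implemented exactly as stated and
left red, as documentation of this behaviour. Consumers of recovered
deformation fields should treat the *tangential* component of the
correspondence as model-determined, not data-determined — the same caveat
that applies to the underlying method.

## Numerical choices

* Curvature: discrete turning angle between successive edges divided by
  the mean adjacent edge length; positive on convex sections; satisfies
  the discrete Gauss–Bonnet identity \(\oint C\,ds_1 = 2\pi\) exactly by
  construction of the weights.
* Arclength origin: the minimum-x (rearmost) vertex, increasing
  anticlockwise, so traction profiles run rear → front along negative y,
  then back along positive y.
* Remeshing commensurability: remeshing an \(m\)-gon to \(n\) spokes with
  \(n \nmid m\) places points on chords, which makes per-point curvature
  oscillate (flat on chords, spiky at original vertices). Tests and
  examples use commensurate counts; pipelines built on spoke-averaged
  outlines are automatically commensurate.
* Ray casting tolerates exact vertex hits by accepting both adjacent edge
  parametrisations and collapsing duplicate intersections within
  \(10^{-9}\) of each other.
* Otsu ties break to the lowest maximising threshold; the returned value
  is the midpoint between the two classes, so `pixels > threshold` is the
  foreground test.
* The degenerate alignment case (rear and front both unmoved) falls back
  to centroid alignment with zero shift.
* TIFF support is a deliberately minimal subset (uncompressed baseline,
  8/16-bit grayscale, multi-page) implemented in-package because no TIFF
  reader exists in the supported dependency set; anything else is rejected
  with a clear error rather than mis-read.

## Limitations

Beyond the recovery caveat above: no viscoelasticity or poroelasticity
(the two models are the elastic extremes); no rupture mechanics (a
threshold-tension flag on shell tractions is available but off by
default); no z-direction tractions; no rotational registration; no
tracking beyond ordered file lists; single-minimum annealing (multi-seed
disagreement is the intended diagnostic for rough landscapes).
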