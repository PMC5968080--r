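---
title: "From focus stacks to measurable 3D models: the disc3d methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From focus stacks to measurable 3D models: the disc3d methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disc3d)
```

## The problem

Pinned insect specimens are photographed from hundreds of directions on a
sphere by a two-axis gimbal, with the camera on a macro rail.  At macro
magnification the depth of field is far smaller than the specimen, so every
view is acquired as a *focus stack* — a sequence of images while the camera
advances along the rail — under two illuminations: a diffuse front-light
dome (near-shadowless reflectance) and a back-light dome (the specimen as a
dark silhouette on a bright ground).  The stacks are merged into extended
depth-of-field (EDOF) images whose geometry must comply with a *single*
pinhole camera model, because everything downstream (photogrammetry,
morphometry) assumes central projection.  `disc3d` implements this
computational chain, and a synthetic scanner that stands in for the
hardware so every stage can be validated against exact ground truth.

## Pose program

The gimbal executes a preassigned pose program: tilt rings at every
multiple of the nominal spacing $\delta$ from $-90^\circ$ to $+90^\circ$,
the ring at tilt $\theta$ holding
$n(\theta) = \operatorname{round}\!\big((360/\delta)\cos\theta\big)$
equally spaced rotation angles, each pole once.  At $\delta = 10^\circ$
this gives 412 poses with a mean nearest-neighbour angular distance of
about $10^\circ$:

```{r poses}
prog <- apply_exclusion(generate_pose_program(10), cone_deg = 15)
prog
mean_nn_distance(prog)
```

Views nearly parallel to the support pin are mechanically and optically
blocked.  We model the blocked set as a symmetric double cone about the
pin axis; the half-angle is a parameter, and its default of $15^\circ$
removes the two polar rings plus poles — 14 poses — leaving 398
accessible.  The true blocked set of the physical device may differ in
identity but not in count; every function takes the cone angle explicitly.

## Rail optics and the slice-scale law

The camera is a central projection with pixel focal length
$f_{px} = m\, z_f / p$ (magnification $m$, focus distance $z_f$, pixel
pitch $p$); the object-side pixel size is $p/m$ (4.37 µm at $m = 1.26$,
$p = 5.5$ µm).  Because the whole camera advances one rail step $\Delta z$
per slice, each slice sees the world from a different projection centre.
Content *in focus* at slice $i$ lies on the plane the camera focuses there,
and mapping it into the perspective of a reference slice $r$ requires an
isotropic rescale about the principal point by the exact projective factor

$$ s_i = \frac{1}{1 + \beta\,(i - r)}, \qquad \beta = \Delta z / z_f . $$

We use the exact form rather than the linear approximation $1 - \beta(i-r)$
because stacks can be long relative to $z_f$.  One consequence worth
stating: $s$ does not obey a multiplicative re-referencing law; what is
exact is that $1/s_i$ is affine in $i$, and re-referencing composes through
$1/s_{i|j} = 1/s_{i|r} - 1/s_{j|r} + 1$.  The reference slice defaults to
the middle of the stack, which minimises the largest rescale and hence
interpolation loss.

**Calibration.** $\beta$ is fitted from a stack of a flat dot-grid target:
per slice, dark dots are segmented (Otsu), border-clipped dots discarded,
and the slice-to-reference image scale $q_i$ estimated by least squares
over matched dot centroids about the principal point.  For a fixed target
and an advancing camera $q_i = z_f/(z_f - \Delta z\,(i-r))$, so $1/q_i$ is
linear in $i$ and a linear regression recovers $\beta$ exactly up to
centroid noise; the per-slice factors $s_i$ are then stored by the
projective law above.  On rendered targets the recovery error is below
0.3% for $\beta \in \{0.002, 0.01, 0.03\}$ at 21 slices.  We fit scale
ratios rather than absolute spacings because the set of visible dots
changes from slice to slice.

## The synthetic scanner

Scenes are analytic solids — spheres, capsules (which also model the
support pin), flat discs — intersected with viewing rays in closed form,
so silhouette areas, depths and projections have exact ground truth.
Surface detail comes from a seeded stationary value-noise field (a sum of
16 random-phase cosine waves with wavenumber $\sim 2\pi/\ell$); amplitude
and correlation length $\ell$ are per-solid parameters.  Front light is
flat ambient shading of the textured albedo — deliberately shadowless,
like a diffuse dome; back light renders solids black on a white ground.

Defocus follows the thin lens: a point at axial distance $z$ viewed by a
camera focused at $z_f$ has circle-of-confusion diameter
$c = f_{px} A \left| 1/z - 1/z_f \right|$ px for entrance pupil $A$.  The
sharp render is split into depth bins one rail step wide *centred* on
multiples of the step (content exactly in focus must receive zero blur),
each bin blurred with $\sigma = c/2$ (clipped at 12 px) and composited
nearest-first with premultiplied alpha.  The default $A = 10$ mm gives
roughly one pixel of blur growth per millimetre of defocus at the default
camera — enough for depth-from-focus to discriminate adjacent slices; a
pinhole ($A = 0$) renders all-in-focus stacks for geometry-only tests.
Rendering is bit-identical for a fixed seed.

What the generator does *not* emulate: specular highlights,
inter-reflection, shadows (the dome suppresses these on the real device),
sensor noise, chromatic effects, and sub-resolution structure such as
setae.  Passing tests therefore demonstrate the correctness of the
geometry and of the algorithms under ideal photometry, not robustness to
real-sensor artefacts.

## EDOF compositing

The compositor follows a winner-take-all depth-from-focus design:

1. every slice is rescaled to the reference perspective by $s_i$
   (bilinear, edge-value fill outside the frame);
2. a focus measure is computed per rescaled slice: Gaussian pre-smooth
   ($\sigma = 1$ px), absolute 3×3 Laplacian, box sum over a 9 px window —
   separable, non-negative, zero on constant images;
3. the per-pixel argmax over slices gives the depth index; ties break
   toward the camera-near slice (occlusion-correct for opaque specimens),
   and the peak is refined to a fractional index by parabolic
   interpolation of the focus measure;
4. the index map is median-filtered (5×5) to suppress salt-and-pepper
   outliers that would otherwise cause halo artefacts;
5. colour is a linear blend of the two slices bracketing the smoothed
   fractional index, removing slice-quantisation banding;
6. pixels whose peak focus response falls below a threshold (Otsu on the
   confidence map, floored at $10^{-4}$ of its maximum) are flagged
   background and filled from the reference slice.

The box window necessarily spreads confidence about half a window beyond
true edges; the resulting halo is irrelevant in the pipeline because the
background is replaced through back-light masking anyway.  On a textured
plane tilted 40° the recovered index map has RMS error ≈ 0.17 slices
(tolerance 0.75); on a two-dot scene spanning ±6 mm of depth, calibrated
compositing reproduces the reference pinhole projection to < 0.2 px where
uncalibrated stacking errs by > 2 px — the property that makes the EDOF
images usable for photogrammetry.

## Masking

The silhouette is segmented from the back-light EDOF image: global Otsu
threshold (overridable with a fixed value), below-threshold pixels as
object, morphological closing (disc, radius 2 px), hole filling, and
removal of components under 50 px.  The support pin is opaque and stays in
the mask by design; it is removed downstream in modelling, outside this
package's scope.  The mask becomes the alpha channel of the front-light
EDOF image; RGB values are untouched and the RGBA round-trips losslessly
through PNG.  Against ground-truth silhouettes of synthetic scans the
masks reach IoU > 0.98 per pose.

## Visual hull

With calibrated masks and known poses, the object is approximated by the
visual hull — the intersection of the silhouette cones of all views.  We
carve a cubic voxel grid: a voxel survives iff its centre projects inside
the image frame *and* inside the silhouette for every view, using the same
extrinsics as the renderer's reference view (one source of truth for
conventions).  Centre-point projection without a conservative footprint is
adequate at ≥ 100³ voxels with ≥ 26 views; the hull contains the true
object up to a sampling margin of half a voxel diagonal plus about one
object-side pixel.  Carving is monotone (more views never enlarge the
hull) and cannot recover concavities — for a torus-like ring scene the
hull volume strictly exceeds the analytic torus volume, which we assert
rather than fight.

The surface is extracted as the exact boundary mesh of the occupied
voxels: two triangles per exposed voxel face, vertices welded on the
corner lattice, outward orientation.  Diagonal voxel contacts (two voxels
sharing only an edge) are healed by filling one adjacent voxel first —
filling only ever adds volume, preserving hull containment — so every mesh
edge is shared by exactly two faces and the enclosed volume equals the
occupied-voxel volume exactly.  We prefer this volume-exact blocky surface
over marching cubes because the downstream measurements are integral
(area, volume), not visual.

## Morphometry and reliability

Surface area is the triangle-area sum; volume is the divergence-theorem
sum of signed origin-tetrahedra, taken as an absolute value so the result
is orientation-independent, and refused (with a boundary-edge count) for
non-watertight input.  Both are invariant under rigid motion to 1e-9 and
scale as $k^2$/$k^3$.  End to end — sphere scene, 26 views, back-light
stacks, EDOF, masks, 128³ carve, surface, volume — the sphere's volume is
recovered within about 1% (tolerance 6%).

Observer reliability uses the coefficient of variation
$\mathrm{CV} = 100\,s/\bar x$ (sample SD, $n-1$), the maximum relative
deviation from the mean $100\,\max|x_i - \bar x|/\bar x$ (computable from
a printed mean and range), and a two-sided variance-ratio test
($F$ = larger/smaller variance).  Full precision is kept internally;
percentages are rounded to 1 d.p. and millimetres to 2 d.p. only at
report time, which is what makes summary-derived CVs reproduce printed
ones.  The bundled 22-observer summary table of two beetle measurements
(`sc`, `ti`; microscope "2D" vs 3D-model) reproduces CVs of 8.0%, 8.3%
and 1.1% and maximum deviations of 5.5% and 2.4%.  Note that one printed
CV (sc, 3D) is not recoverable from its own printed summary
(100·0.07/2.72 = 2.6%) — a reminder that such tables are rounded — and
printed $F$ statistics require unrounded SDs, so only the $p < 10^{-4}$
bound is checked.

## Numerical choices and problem sizes

* Reference slice: middle of the stack; background fill: reference slice.
* Median filter radius 2 (5×5); focus window 9 px; both configurable.
* Degenerate geometry ($1 + \beta(i-r) \le 0$) and non-watertight meshes
  raise errors rather than warnings.
* Test scenes use 96–192 px images, 5–21 slices, 48–128³ grids and up to
  26 views — small enough for a laptop, large enough that every tolerance
  above is met with margin; the same constructions scale to the full
  2048² / 398-pose geometry unchanged.
* Everything stochastic (textures, seeds) is derived from one integer
  seed; two runs with the same configuration produce bit-identical PNGs.

## Known limitations

* The blocked-pose model (double cone) matches the published count, not a
  documented pose list.
* Depth-from-focus needs texture: on texture-free surfaces the confidence
  threshold marks them background; real specimens are texture-rich.
* The visual hull is an outer bound; concave regions are not recovered
  (inherent to shape-from-silhouette, not to this implementation).
* The blocky surface is volume-exact but not smooth: its *area*
  carries the voxel staircase bias (up to ~50% high on smooth objects),
  so hull surface areas should be read as upper bounds; area measured on
  externally supplied meshes (OBJ) has no such bias.  Do not use the
  hull surface for curvature-based measures.
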