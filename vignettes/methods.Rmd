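---
title: "Methods: image-to-FE modelling of vertebral cement augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-to-FE modelling of vertebral cement augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vertebrofe` turns a high-resolution CT scan of a potted lumbar vertebral
body into a solvable voxel finite-element model of its axial compression
stiffness, before and after cement augmentation, and calibrates the single
free material parameter against experimental stiffness. This vignette
records the model, its assumptions, the parameters that matter, the
synthetic phantom used for verification, and the numerical choices made
where the design was genuinely open.

## The mechanical model

The vertebra is treated as an isotropic, linear elastic, small-strain
continuum sampled on a regular 1 mm voxel grid. Each retained voxel
becomes one trilinear 8-node hexahedral element (2×2×2 Gauss
integration). Six element classes exist: bone, cement, interface, needle
track, and the two PMMA potting endcaps.

**Bone.** The element modulus is mapped linearly from the local image
value: `E = 255 · k · g` GPa, where `g ∈ [0, 1]` is the coarse voxel's
fraction value and `k` (GPa per 8-bit grayscale unit) is the single
calibrated parameter. The factor 255 keeps `k` on the per-grayscale-unit
scale conventional for 8-bit pipelines while fields are stored in
`[0, 1]`. Two routes produce `g`:

* *direct grayscale* — block-mean downsampling of the raw scan divided by
  255. Marrow intensity deliberately stays in the field.
* *bone volume fraction (BV/TV)* — the scan is binarised at the cohort
  threshold first, then block-mean downsampled, so `g` is exactly the
  local bone volume fraction and marrow never enters. Block means make
  the binary route conservative: total bone volume is preserved to float
  precision, which the tests assert.

Voxels whose mapped modulus falls below a floor of `1e-6` GPa keep the
floor instead of being deleted. This keeps mesh topology independent of
`k` (the calibration objective stays continuous) and the system
nonsingular. Bone Poisson ratio defaults to 0.3, the standard continuum
value for trabecular bone models; it is exposed as a parameter because
the source protocols rarely print it.

**Non-bone cards.** PMMA endcaps 2.45 GPa / ν 0.3; augmentation cement
1.7 GPa / ν 0.4; cement–bone interface 0.01 GPa / ν 0.4 with a perfectly
plastic von Mises yield at 5 Pa. The interface layer — one coarse voxel
(1 mm) of dilation shell around the cement, restricted to the body —
represents, at continuum scale, trabeculae at the cement border that are
only partially constrained by cement: almost no deviatoric strength, but
full (elastic) volumetric support. Needle-track voxels get the floor
modulus (void).

**Boundary conditions.** The exterior surface of the inferior endcap is
fully fixed (encastre). The superior endcap's top surface is
kinematically tied to a rigid platen whose axial translation is
prescribed (default 1 mm compression), lateral translations fixed, and
tilt rotations free about the marked load point — emulating load applied
through a steel ball. Model stiffness is the platen reaction divided by
the prescribed displacement (N/mm).

The endcap–bone interfaces are modelled as frictionless, no-separation
contact linearised to a node-coincident tie of the axial degree of
freedom only: the interface nodes are duplicated so endcap elements keep
independent lateral displacements. Compression keeps separation inactive,
so the linear tie is exact for this load case. Two consequences follow
and are handled explicitly:

* the platen's *spin* about the load axis transmits no load through a
  frictionless interface and is therefore a zero-energy mode; it is held
  at zero (the ball joint cannot transmit torque anyway, so this does not
  change the reaction);
* the body itself could drift laterally or spin at zero energy; two body
  nodes at the inferior interface are pinned laterally, positioned so the
  pins are consistent with a uniform deformation field (they carry no
  force for a homogeneous column, which the closed-form tests confirm).

## Segmentation and threshold selection

The trabecular segmentation threshold is chosen by maximising the
connectivity `Conn = 1 − χ` of the thresholded stack over a grayscale
sweep, where the Euler characteristic `χ = V − E + F − C` is computed
exactly from the cubical complex of the 26-connected foreground. The
per-specimen optima are averaged into a single cohort threshold. Ties on
the connectivity plateau break toward the lowest threshold. The sweep
bounds and step are configuration parameters (defaults 40–220, step 10 on
the 8-bit scale).

A caveat the phantom experiments made explicit: for thin struts near the
sampling limit, connectivity peaks *below* the 50% grayscale crossing,
because at mid-level thresholds sub-voxel struts fragment (each break
costs a loop) while slightly lower thresholds keep the full network
connected. The selected threshold is therefore validated as separating
the marrow and bone intensity classes and recovering the ground-truth
network, not as matching the rendering midpoint.

The body mask — which voxels become elements — is taken from the
*direct-grayscale* field for both material routes (largest 26-connected
component above a floor of 0.06): marrow intensity makes the body solid
there, whereas the BV/TV field would leave holes in pure-marrow blocks.

## Augmented models

Three variants are first-class flags:

* `post_only`: everything, including the bone field, comes from the
  augmented scan. The bright halo around cement then inflates the
  apparent bone density — this variant exists as the degraded baseline.
* `registered`: the bone field and body mask come from the
  pre-augmentation scan; the cement mask is segmented from the augmented
  scan at fine resolution (small components removed as opacifier
  speckle), mapped into pre space by the rigid transform fitted to three
  anatomical landmarks, and converted to coarse elements by majority
  occupancy (≥ 0.5). The landmark fit is the closed-form cross-covariance
  SVD (Kabsch) solution with reflection correction; three well-spread
  landmarks determine the motion exactly, and noiseless configurations
  are recovered to machine precision.
* `registered_with_needle_tracks`: additionally, a user-supplied needle
  mask (manual segmentation in practice; the generator's ground truth on
  phantoms) is carved into the mesh as void elements, with precedence
  cement > interface > needle > bone.

## The elastoplastic solve

Elastic solves assemble the sparse symmetric stiffness, eliminate all
constraints (fixed dofs, the platen's rigid-body coupling, the axial
ties) through an explicit transformation matrix — exactness over penalty
tuning — and factorise with a supernodal sparse Cholesky. On voxel meshes
every element shares its geometry, so the element stiffness splits into
two precomputed 24×24 matrices scaled by the Lamé parameters, and
assembly is a vectorised scaling.

With the yielding interface active, loading proceeds in a monotonic
displacement ramp (default 10 increments). Each interface Gauss point
follows J2 perfect plasticity via radial return; equilibrium within an
increment uses full Newton iterations with the algorithmically consistent
tangent, refactorised per iteration. Modified Newton with the elastic
tangent was tried first and stalls: at 5 Pa the interface's deviatoric
strength is ~7 orders below its elastic stiffness, which makes the
elastic tangent a uselessly stiff preconditioner. The yield surface is a
configuration choice isolated in the material card, so a different
criterion could be swapped in.

Calibration re-solves every build model at each candidate `k`. Because
the stiffness matrix is exactly affine in `k` away from the floor regime
(`K = k·A + B`), each model's assembly and symbolic analysis happen once
and each candidate costs one numeric refactorisation; the evaluator
falls back to full reassembly if a candidate would floor any nonzero
bone element, so the optimisation is exact. The 1-D objective (RMS
percentage error by default; maximise-CCC switchable) is minimised by
golden-section search on user bounds (defaults 1e-4 to 1e-2 GPa per
grayscale unit), with the bracket converged below 1e-3 relative and
bound-pinned optima flagged.

## The synthetic phantom

The generator emulates the cadaveric protocol: an elliptical-cylinder
vertebral body (defaults 17 × 14 mm semi-axes, 25 mm height — typical
lumbar dimensions) with a solid cortical shell (0.5 mm) and an interior
trabecular lattice, potted in PMMA slabs, scanned at isotropic fine
resolution (default 0.082 mm), with three non-collinear surface landmarks
and a load point over the superior endcap. The lattice is the union of
three orthogonal sinusoidal strut families, tilted by a small seeded
rotation so the struts are neither grid-aligned nor commensurate with the
voxel lattice (real trabeculae are not axis-aligned; the tilt also makes
occupancy effectively continuous in the threshold parameter). Interior
occupancy is tuned by bisection to the target BV/TV; the cadaveric range
0.127–0.391 is reachable and covered in the tests.

Rendering composes tissue intensity levels (marrow 30, bone 180, endcap
140, cement 240 on the 8-bit scale), adds Gaussian acquisition noise
(default σ = 10), and applies a Gaussian point-spread blur (default 0.7
voxel), in that order — so the rendered noise is spatially correlated and
tissue boundaries show partial-volume transitions, as in tomographic
reconstructions. Augmentation places either one ellipsoidal blob
(concentrated) or many small blobs (dispersed) sized to the target fill
fraction, carves an oblique needle cylinder, optionally adds a bright
halo ring around the cement, and renders the post scan in a frame moved
by a small random rigid perturbation (≤ 3°, ≤ 1 mm) that is stored and
maps the pre landmarks exactly onto the post landmarks.

What the phantom does **not** emulate — hence what passing tests do not
show about real data: vertebral anatomy beyond an elliptical body (no
pedicles or posterior elements; the landmarks are plausible surface
points, not anatomical ones), beam hardening and scatter, cement
rheology and leakage, plate-like trabecular architecture and anisotropy,
and inter-scanner intensity calibration. Dispersed fills are generated as
random blobs, not flow physics — they exercise the segmentation and
meshing paths, not the physics of dispersed augmentation.

## Numerical choices and degenerate inputs

* Block downsampling zero-pads non-divisible dimensions at the high-index
  end and records the pad; intensity conservation stays exact.
* Dilation uses the 26-connected 3×3×3 structuring element, applied
  radius-many times.
* Fine-to-coarse mask conversion is a majority vote (occupancy ≥ 0.5) —
  symmetric between foreground and background.
* Empty cement segmentations warn and return a valid empty mask
  (non-augmented controls).
* Lin's CCC uses population (1/n) moments; both-constant-equal pairs
  define CCC = 1, both-constant-unequal 0.
* The even build/validation split is seeded-random; sizes differ by at
  most one.
* Curve stiffness uses OLS window slopes (20 points) rather than endpoint
  differences, for noise robustness; windows with zero displacement span
  are an error.

## Problem sizes used for verification

The test and verification suites run on scaled-down study conditions
chosen to exercise every stage at interactive cost: phantom bodies of
6 × 5 × 10 mm to 8 × 6.5 × 14 mm at 0.25 mm fine and 1 mm coarse
resolution (roughly 1,000–5,000 elements per model), cohorts of 4–6
specimens, and 50 noise replicates for the calibration study. The
acceptance script uses the 8 × 6.5 × 14 mm cohort. One consequence of the
reduced body size is that the fixed 1 mm interface shell is proportionally
much thicker than in a full-size vertebra, so the predicted stiffness
change after augmentation skews negative relative to what full-size
models would give; the script reports the computed range without claiming
correspondence to cadaveric values.

## Known limitations

* Pure voxel-hex meshes (no surface-smoothing tetrahedra) introduce
  stair-step surfaces; this is a documented deviation from smoothed
  hex/tet meshing and a known source of surface-stiffness deviation.
* Geometric nonlinearity, contact search, bone anisotropy, hardening and
  fracture are out of scope; the interface is the only nonlinearity.
* CCC and RMS statistics on real cadaveric data require the external
  specimen dataset; everything here is verified against closed forms,
  brute-force oracles and phantom ground truth instead.
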