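# vertebrofe

Specimen-specific voxel finite-element models of human lumbar vertebrae
before and after cement augmentation (vertebroplasty), built from
micro-CT-style image stacks.

Vertebroplasty stabilises osteoporotic compression fractures by injecting
PMMA cement into the vertebral body, but its mechanical effect varies
widely between patients. Image-based finite-element (FE) models predict a
vertebra's axial stiffness from a calibrated scan, and — once validated
against cadaveric compression tests — let one ask how cement volume,
distribution and needle damage change that stiffness. `vertebrofe`
implements such a pipeline end to end for researchers in computational
bone biomechanics: image I/O and resampling, connectivity-based threshold
selection, two bone material-mapping routes, three-landmark rigid
registration of pre- and post-augmentation scans, voxel-hexahedral meshing
with an elastic–perfectly-plastic cement–bone interface, a sparse FE
solver, and the calibration/validation statistics. A synthetic vertebra
phantom generator with known ground truth makes every stage verifiable
without cadaveric data.

## The model

* **Stiffness (experiment).** From an axial load–displacement curve
  (ramp to 1600 N), specimen stiffness is the maximum gradient over
  sliding windows of 20 samples, each slope fitted by ordinary least
  squares: `S = max_i slope(d[i:i+19], F[i:i+19])` (N/mm).
* **Material mapping.** The scan (82 µm isotropic in the reference
  protocol) is reduced to a 1 mm background either by direct block
  averaging of grayscale (*direct grayscale* route) or by thresholding the
  trabeculae first and averaging the binary mask, so each coarse voxel
  holds its bone volume fraction BV/TV (*bone volume fraction* route).
  The segmentation threshold maximises the Euler-characteristic-based
  connectivity `Conn = 1 − χ` of the trabecular network over a grayscale
  sweep, averaged across the cohort.
* **Elements.** One 8-node hexahedron per coarse voxel. Bone elements are
  isotropic linear elastic with `E = 255·k·g` (GPa), where `g ∈ [0,1]` is
  the voxel's fraction value and `k` the conversion factor in GPa per
  grayscale unit; empty voxels keep a floor modulus of 1e-6 GPa. PMMA
  endcaps: 2.45 GPa, ν 0.3. Cement: 1.7 GPa, ν 0.4. The 1 mm cement–bone
  interface shell: 0.01 GPa, ν 0.4, von Mises yield 5 Pa, perfectly
  plastic (J2 radial return) — a continuum stand-in for trabeculae only
  partially constrained by cement.
* **Augmented models.** The bone field comes from the registered
  pre-augmentation scan (a closed-form 3-landmark Kabsch fit maps the
  post scan into pre space), the cement mask from the post scan
  (segmented at fine resolution, majority-vote downsampled), and needle
  tracks are carved as void elements — avoiding the bright cement halo
  that corrupts post-scan bone segmentation.
* **Loading.** Inferior endcap surface encastre; superior endcap tied to
  a rigid platen driven 1 mm axially through a ball joint at the marked
  load point (tilt rotations free, lateral translations fixed). Model
  stiffness = platen reaction / prescribed displacement.
* **Calibration.** `k` is fitted by bounded golden-section minimisation of
  the RMS percentage error between FE and experimental stiffness on a
  build split, then applied to the held-out validation split; agreement is
  summarised by Lin's concordance correlation coefficient
  `CCC = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` and the RMS % error.

## Worked example

Generate a synthetic vertebra, augment it, and run the calibration
pipeline on a small phantom cohort whose "experimental" stiffness was
produced by the model at `k = 9e-4` with 10% specimen-level noise:

```r
library(vertebrofe)

spec <- phantom_spec(body_semiaxes = c(8, 6.5), body_height = 14,
                     endcap_thickness = 3, fine_spacing = 0.25,
                     target_bvtv = 0.22, seed = 42)
rec <- generate_vertebra_phantom(spec)
rec
#> <specimen_record> 68 x 56 x 80 fine voxels @ 0.25 mm, BV/TV 0.220
#>   augmented: no; experimental stiffness: none

rec <- inject_cement(rec, cement_spec("concentrated", fill_fraction = 0.3))
cement <- segment_cement(rec$post_image, cement_threshold = 210)
dice_overlap(cement, rec$true_cement_mask)
#> [1] 0.946
fit_rigid(rec$landmarks_post, rec$landmarks_pre)
#> <rigid_transform> rotation 2.759 deg, translation (-0.130, 0.013, 0.459) mm

cohort <- lapply(1:4, function(i) generate_vertebra_phantom(
  phantom_spec(body_semiaxes = c(8, 6.5), body_height = 14,
               endcap_thickness = 3, fine_spacing = 0.25,
               target_bvtv = c(0.15, 0.2, 0.27, 0.33)[i], seed = i)))
names(cohort) <- paste0("phantom", 1:4)
cfg <- pipeline_config()           # bvtv + registration + needle tracks
cohort <- synthesize_experiments(cohort, cfg, k_true = 9e-4, noise_cv = 0.1)
res <- run_pipeline(cohort, cfg, quiet = TRUE)
res
#> <pipeline_result> bvtv / registered_with_needle_tracks, 4 specimens
#>   k (build) = 0.00083235, k (all) = 0.00089188 GPa/grayscale
#>   validation CCC 0.634 RMS 15.5% | full CCC 0.875 RMS 8.9%
```

The recovered conversion factor (`0.00089` GPa per grayscale unit) sits
within 1% of the generating value on the full cohort; the per-specimen
table, split labels and a reproducibility manifest are in `res`.
`summary(res$calibration_full)` prints predicted vs experimental stiffness
per specimen, and `plot(res$calibration_full)` draws the agreement against
the identity line.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/vertebrofe.R phantom --seed 1 --out runs/p1 --bvtv 0.2 --cement-fill 0.3
Rscript inst/cli/vertebrofe.R run --cohort runs --out runs/result
```

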