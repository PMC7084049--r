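#' Specification of a synthetic vertebra phantom
#'
#' The phantom emulates an HR-pQCT scan of a potted lumbar vertebral body:
#' an elliptical-cylinder body with a solid cortical shell and a
#' trabecular-like interior lattice of three orthogonal sinusoidal strut
#' families, capped by two PMMA potting slabs. Default dimensions are
#' typical of a human lumbar vertebral body (semi-axes 17 x 14 mm, height
#' 25 mm) scanned at 82 um isotropic resolution; the defaults for target
#' BV/TV span the osteoporotic-to-normal range observed in cadaveric
#' lumbar specimens (about 0.13-0.39).
#'
#' @param body_semiaxes lateral/antero-posterior semi-axes (mm); +y is
#'   anterior.
#' @param body_height vertebral body height (mm).
#' @param shell_thickness cortical shell thickness (mm).
#' @param target_bvtv target interior bone volume fraction, in (0, 1).
#' @param strut_period trabecular lattice spacing (mm).
#' @param endcap_thickness PMMA endcap slab thickness (mm).
#' @param fine_spacing scan voxel size (mm); 0.082 matches HR-pQCT.
#' @param noise_sd grayscale noise standard deviation (8-bit units).
#' @param psf_sigma scanner point-spread blur, in voxels (Gaussian standard
#'   deviation applied to the rendered intensities before noise); emulates
#'   the partial-volume transition between marrow and bone that real
#'   tomographic images show at trabecular boundaries.
#' @param bone_level,marrow_level,endcap_level rendering intensities (8-bit).
#' @param seed integer RNG seed; all phantom randomness flows from it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_semiaxes = c(17, 14), body_height = 25,
                         shell_thickness = 0.5, target_bvtv = 0.2,
                         strut_period = 1.0, endcap_thickness = 5,
                         fine_spacing = 0.082, noise_sd = 10,
                         psf_sigma = 0.7, bone_level = 180,
                         marrow_level = 30, endcap_level = 140, seed = 1L) {
  stopifnot(length(body_semiaxes) == 2L, all(body_semiaxes > 0),
            body_height > 0, shell_thickness >= fine_spacing,
            target_bvtv > 0, target_bvtv < 1, strut_period > 0,
            endcap_thickness > 0, fine_spacing > 0, noise_sd >= 0,
            psf_sigma >= 0)
  structure(list(body_semiaxes = body_semiaxes, body_height = body_height,
                 shell_thickness = shell_thickness, target_bvtv = target_bvtv,
                 strut_period = strut_period,
                 endcap_thickness = endcap_thickness,
                 fine_spacing = fine_spacing, noise_sd = noise_sd,
                 psf_sigma = psf_sigma,
                 bone_level = bone_level, marrow_level = marrow_level,
                 endcap_level = endcap_level, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specification of a synthetic cement injection
#'
#' @param mode `"concentrated"` (single coherent blob, the well-modelled
#'   case) or `"dispersed"` (many small pockets, the case real cement takes
#'   when it follows the trabecular spaces).
#' @param fill_fraction target cement volume as a fraction of the vertebral
#'   body volume, in (0, 1); cadaveric fills span roughly 0.03-0.55.
#' @param centroid blob centre (mm), `NULL` = anterior centre of the body.
#' @param needle_entry direction of the oblique needle approach (unit not
#'   required), `NULL` = posterolateral oblique default.
#' @param needle_radius cannula radius (mm).
#' @param cement_level rendered cement intensity (8-bit).
#' @param halo if `TRUE`, render a bright halo ring around the cement (the
#'   blooming artifact that corrupts post-augmentation bone segmentation).
#' @param halo_level halo intensity (8-bit).
#' @param max_rotation_deg,max_translation_mm bounds of the random rigid
#'   perturbation between the pre- and post-augmentation scan frames.
#' @return object of class `cement_spec`.
#' @export
cement_spec <- function(mode = c("concentrated", "dispersed"),
                        fill_fraction = 0.3, centroid = NULL,
                        needle_entry = NULL, needle_radius = 1.5,
                        cement_level = 240, halo = FALSE, halo_level = 160,
                        max_rotation_deg = 3, max_translation_mm = 1) {
  mode <- match.arg(mode)
  stopifnot(fill_fraction >= 0, fill_fraction < 1, needle_radius > 0)
  structure(list(mode = mode, fill_fraction = fill_fraction,
                 centroid = centroid, needle_entry = needle_entry,
                 needle_radius = needle_radius, cement_level = cement_level,
                 halo = halo, halo_level = halo_level,
                 max_rotation_deg = max_rotation_deg,
                 max_translation_mm = max_translation_mm),
            class = "cement_spec")
}

# separable Gaussian blur with sd `sigma` voxels; edges are replicated so
# flat regions keep their level
gaussian_blur3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    idx_all <- seq_len(d[ax])
    for (s in (-r):r) {
      idx <- pmin(pmax(idx_all + s, 1L), d[ax])
      shifted <- switch(ax,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[s + r + 1L] * shifted
    }
    arr <- out
  }
  arr
}

# physical coordinate vectors of a phantom grid (x, y, z voxel centres)
phantom_grid <- function(spec) {
  h <- spec$fine_spacing
  margin <- 2 * h
  a <- spec$body_semiaxes[1] + margin
  b <- spec$body_semiaxes[2] + margin
  zlen <- spec$body_height + 2 * spec$endcap_thickness
  nx <- as.integer(ceiling(2 * a / h))
  ny <- as.integer(ceiling(2 * b / h))
  nz <- as.integer(ceiling(zlen / h))
  origin <- c(-(nx - 1) / 2 * h, -(ny - 1) / 2 * h, h / 2)
  list(shape = c(nx, ny, nz), spacing = h, origin = origin,
       x = origin[1] + (seq_len(nx) - 1) * h,
       y = origin[2] + (seq_len(ny) - 1) * h,
       z = origin[3] + (seq_len(nz) - 1) * h,
       z_body = c(spec$endcap_thickness,
                  spec$endcap_thickness + spec$body_height))
}

# broadcast per-axis vectors over the full grid
grid_expand <- function(g) {
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  list(X = array(rep.int(g$x, ny * nz), c(nx, ny, nz)),
       Y = array(rep.int(rep(g$y, each = nx), nz), c(nx, ny, nz)),
       Z = array(rep(g$z, each = nx * ny), c(nx, ny, nz)))
}

# Lattice of three orthogonal strut families; occupancy grows as `level`
# drops. The lattice frame is tilted by a small rotation so the struts are
# not aligned (or commensurate) with the voxel grid: real trabeculae are
# not grid-aligned, and the tilt also makes the occupancy-vs-level curve
# effectively continuous, which the bisection tuning relies on.
strut_lattice <- function(G, period, phases, level, tilt = diag(3)) {
  w <- 2 * pi / period
  X <- tilt[1, 1] * G$X + tilt[1, 2] * G$Y + tilt[1, 3] * G$Z
  Y <- tilt[2, 1] * G$X + tilt[2, 2] * G$Y + tilt[2, 3] * G$Z
  Z <- tilt[3, 1] * G$X + tilt[3, 2] * G$Y + tilt[3, 3] * G$Z
  fz <- cos(w * X + phases[1]) + cos(w * Y + phases[2])
  fx <- cos(w * Y + phases[3]) + cos(w * Z + phases[4])
  fy <- cos(w * X + phases[5]) + cos(w * Z + phases[6])
  (fz >= level) | (fx >= level) | (fy >= level)
}

#' Generate a synthetic vertebra phantom (pre-augmentation scan)
#'
#' Builds the fine-resolution binary bone structure (solid cortical shell
#' plus interior strut lattice), tunes lattice occupancy by bisection so the
#' measured interior BV/TV is within 0.02 of `spec$target_bvtv`, renders an
#' 8-bit-range grayscale scan with Gaussian noise and a marrow background,
#' appends PMMA endcap slabs, and places three non-collinear surface
#' landmarks (posterolateral superior, posterolateral inferior on the
#' opposite side, and anterior inferior). Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `specimen_record` with fields `pre_image`,
#'   `landmarks_pre`, `load_point`, `endcap_masks` (fine masks, bottom/top),
#'   ground-truth `true_bone_mask_pre` and `interior_mask_pre`, the
#'   `render_threshold` (midpoint of marrow and bone levels), `measured_bvtv`
#'   and the generating `spec`.
#' @export
generate_vertebra_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- phantom_grid(spec)
  G <- grid_expand(g)
  a <- spec$body_semiaxes[1]; b <- spec$body_semiaxes[2]
  in_body_z <- G$Z > g$z_body[1] & G$Z < g$z_body[2]
  r2 <- (G$X / a)^2 + (G$Y / b)^2
  in_ellipse <- r2 <= 1
  ai <- a - spec$shell_thickness; bi <- b - spec$shell_thickness
  in_interior <- (G$X / ai)^2 + (G$Y / bi)^2 <= 1
  shell <- in_ellipse & !in_interior & in_body_z
  interior <- in_interior & in_body_z

  phases <- stats::runif(6, 0, 2 * pi)
  tilt <- rotation_about(stats::rnorm(3), stats::runif(1, 4, 9))$rotation
  n_int <- sum(interior)
  bvtv_at <- function(level) {
    lat <- strut_lattice(G, spec$strut_period, phases, level, tilt)
    sum(lat & interior) / n_int
  }
  lo <- -2; hi <- 2
  if (bvtv_at(lo) < spec$target_bvtv || bvtv_at(hi) > spec$target_bvtv)
    stop(sprintf(
      "target BV/TV %.3f unreachable for strut period %.2f mm at %.3f mm voxels",
      spec$target_bvtv, spec$strut_period, spec$fine_spacing))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (bvtv_at(mid) >= spec$target_bvtv) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  lattice <- strut_lattice(G, spec$strut_period, phases, lo, tilt)
  bone <- shell | (lattice & interior)
  measured_bvtv <- sum(bone & interior) / n_int

  endcap_bottom <- in_ellipse & G$Z <= g$z_body[1]
  endcap_top <- in_ellipse & G$Z >= g$z_body[2]

  gray <- array(spec$marrow_level, g$shape)
  gray[bone] <- spec$bone_level
  gray[endcap_bottom | endcap_top] <- spec$endcap_level
  # acquisition noise enters before the reconstruction blur, so the
  # rendered noise is spatially correlated as in real tomographic images
  if (spec$noise_sd > 0)
    gray <- gray + stats::rnorm(length(gray), 0, spec$noise_sd)
  gray <- gaussian_blur3(gray, spec$psf_sigma)
  gray <- array(pmin(pmax(gray, 0), 255), g$shape)

  ellipse_pt <- function(theta_deg, zfrac) {
    th <- theta_deg * pi / 180
    c(a * cos(th), b * sin(th), g$z_body[1] + zfrac * spec$body_height)
  }
  landmarks <- rbind(post_left_sup = ellipse_pt(215, 0.85),
                     post_right_inf = ellipse_pt(325, 0.15),
                     ant_inf = ellipse_pt(90, 0.10))

  mk <- function(m) voxel_image(array(as.numeric(m), g$shape), g$spacing,
                                g$origin)
  structure(list(
    pre_image = voxel_image(gray, g$spacing, g$origin),
    post_image = NULL,
    landmarks_pre = landmarks,
    landmarks_post = NULL,
    load_point = c(0, 0, max(g$z) + g$spacing / 2),
    experimental_stiffness = NA_real_,
    true_bone_mask_pre = mk(bone),
    interior_mask_pre = mk(interior),
    endcap_masks = list(bottom = mk(endcap_bottom), top = mk(endcap_top)),
    true_cement_mask = NULL, true_needle_mask = NULL,
    true_cement_mask_pre = NULL, true_needle_mask_pre = NULL,
    perturbation = NULL,
    render_threshold = (spec$marrow_level + spec$bone_level) / 2,
    measured_bvtv = measured_bvtv,
    spec = spec, cement_spec = NULL),
    class = "specimen_record")
}

#' @export
print.specimen_record <- function(x, ...) {
  d <- dim(x$pre_image$data)
  cat(sprintf("<specimen_record> %d x %d x %d fine voxels @ %g mm, BV/TV %.3f\n",
              d[1], d[2], d[3], x$pre_image$spacing, x$measured_bvtv))
  cat(sprintf("  augmented: %s; experimental stiffness: %s\n",
              if (is.null(x$post_image)) "no" else x$cement_spec$mode,
              if (is.na(x$experimental_stiffness)) "none"
              else sprintf("%.1f N/mm", x$experimental_stiffness)))
  invisible(x)
}

# volume fraction of mask within the body region
fill_fraction_of <- function(mask, body) sum(mask & body) / sum(body)

#' Inject synthetic cement and render the post-augmentation scan
#'
#' In the pre-augmentation frame, places either a single ellipsoidal cement
#' blob (concentrated) or many small blobs (dispersed) sized so the achieved
#' fill fraction is within 0.05 of `cspec$fill_fraction`, carves an oblique
#' needle track from the posterolateral shell to the blob centroid, then
#' renders the post-augmentation scan in a new frame related to the
#' pre-augmentation frame by a small random rigid perturbation (stored in
#' the record; it maps pre landmarks exactly onto post landmarks). Cement is
#' rendered at high intensity, optionally with a surrounding bright halo.
#' With `fill_fraction = 0` the post image is simply the rigidly moved pre
#' image with empty cement and needle masks.
#'
#' @param rec a `specimen_record` from [generate_vertebra_phantom()].
#' @param cspec a [cement_spec()].
#' @return the record with `post_image`, `landmarks_post`, ground-truth
#'   cement/needle masks (in both frames) and the pre-to-post `perturbation`
#'   filled in.
#' @export
inject_cement <- function(rec, cspec) {
  stopifnot(inherits(rec, "specimen_record"), inherits(cspec, "cement_spec"))
  if (is.null(rec$pre_image)) stop("record has no pre-augmentation image")
  spec <- rec$spec
  set.seed(spec$seed + 104729L)  # independent stream from the generator
  g <- phantom_grid(spec)
  G <- grid_expand(g)
  a <- spec$body_semiaxes[1]; b <- spec$body_semiaxes[2]
  in_body_z <- G$Z > g$z_body[1] & G$Z < g$z_body[2]
  body <- ((G$X / a)^2 + (G$Y / b)^2 <= 1) & in_body_z
  bone <- rec$true_bone_mask_pre$data > 0
  centre_z <- mean(g$z_body)
  centroid <- cspec$centroid %||% c(0, 0.35 * b, centre_z)

  cement <- array(FALSE, g$shape)
  if (cspec$fill_fraction > 0) {
    if (cspec$mode == "concentrated") {
      blob_at <- function(s) {
        ((G$X - centroid[1]) / s)^2 + ((G$Y - centroid[2]) / (0.85 * s))^2 +
          ((G$Z - centroid[3]) / (0.7 * s))^2 <= 1
      }
      lo <- spec$fine_spacing; hi <- 2 * max(a, b, spec$body_height)
      if (fill_fraction_of(blob_at(hi) & body, body) <
          cspec$fill_fraction - 0.05)
        stop("cement fill target exceeds the available cavity volume")
      for (it in 1:50) {
        mid <- (lo + hi) / 2
        if (fill_fraction_of(blob_at(mid) & body, body) <
            cspec$fill_fraction) lo <- mid else hi <- mid
      }
      cement <- blob_at(hi) & body
    } else {
      interior <- rec$interior_mask_pre$data > 0
      achieved <- 0
      tries <- 0L
      while (achieved < cspec$fill_fraction - 0.01 && tries < 4000L) {
        tries <- tries + 1L
        ctr <- c(stats::runif(1, -0.8 * a, 0.8 * a),
                 stats::runif(1, -0.4 * b, 0.9 * b),
                 stats::runif(1, g$z_body[1] + 0.15 * spec$body_height,
                              g$z_body[2] - 0.15 * spec$body_height))
        if ((ctr[1] / a)^2 + (ctr[2] / b)^2 > 0.7) next
        r <- stats::runif(1, 0.8, 1.8) * spec$strut_period
        blob <- ((G$X - ctr[1])^2 + (G$Y - ctr[2])^2 +
                   (G$Z - ctr[3])^2) <= r^2
        cement <- cement | (blob & interior)
        achieved <- fill_fraction_of(cement, body)
      }
      if (achieved < cspec$fill_fraction - 0.05)
        stop("dispersed cement fill target exceeds the available cavity volume")
    }
  }

  needle <- array(FALSE, g$shape)
  if (cspec$fill_fraction > 0) {
    # direction from the posterolateral entry point toward the blob centroid
    entry_dir <- cspec$needle_entry %||% c(0.5, 1, 0.2)
    entry_dir <- entry_dir / sqrt(sum(entry_dir^2))
    # ray from the centroid opposite to the approach direction hits the shell
    tip <- centroid
    axis <- entry_dir
    rel <- cbind(as.vector(G$X) - tip[1], as.vector(G$Y) - tip[2],
                 as.vector(G$Z) - tip[3])
    tpar <- rel %*% axis
    d2 <- rowSums(rel^2) - tpar^2
    needle <- array(tpar <= 0 & d2 <= cspec$needle_radius^2, g$shape) & body
    needle <- needle & !cement  # precedence: cement wins over the track
  }
  bone_post <- bone & !needle

  # random rigid perturbation between the two scanning sessions
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0.3, 1) * cspec$max_rotation_deg
  tvec <- stats::runif(3, -1, 1) * cspec$max_translation_mm
  centre <- c(0, 0, mean(g$z))
  pert <- rotation_about(axis, ang, centre = centre, translation = tvec)

  mk <- function(m) voxel_image(array(as.numeric(m), g$shape), g$spacing,
                                g$origin)
  tgt <- grid_spec(g$shape, g$spacing, g$origin)
  move <- function(m) resample_nearest(mk(m), pert, tgt)$data > 0
  bone_p <- move(bone_post)
  cement_p <- move(cement)
  needle_p <- move(needle)
  cap_b_p <- move(rec$endcap_masks$bottom$data > 0)
  cap_t_p <- move(rec$endcap_masks$top$data > 0)

  gray <- array(spec$marrow_level, g$shape)
  gray[bone_p] <- spec$bone_level
  gray[cap_b_p | cap_t_p] <- spec$endcap_level
  if (cspec$halo && any(cement_p)) {
    halo_r <- max(1L, as.integer(round(0.5 / g$spacing)))
    ring <- dilate_mask(mk(cement_p), halo_r)$data > 0 & !cement_p & !bone_p
    gray[ring] <- cspec$halo_level
  }
  gray[cement_p] <- cspec$cement_level
  if (spec$noise_sd > 0)
    gray <- gray + stats::rnorm(length(gray), 0, spec$noise_sd)
  gray <- gaussian_blur3(gray, spec$psf_sigma)
  gray <- array(pmin(pmax(gray, 0), 255), g$shape)

  rec$post_image <- voxel_image(gray, g$spacing, g$origin)
  rec$landmarks_post <- apply_transform(pert, rec$landmarks_pre)
  rownames(rec$landmarks_post) <- rownames(rec$landmarks_pre)
  rec$endcap_masks_post <- list(bottom = mk(cap_b_p), top = mk(cap_t_p))
  rec$true_cement_mask <- mk(cement_p)
  rec$true_needle_mask <- mk(needle_p)
  rec$true_cement_mask_pre <- mk(cement)
  rec$true_needle_mask_pre <- mk(needle)
  rec$perturbation <- pert
  rec$cement_spec <- cspec
  rec$achieved_fill <- fill_fraction_of(cement, body)
  rec
}

#' Simulate an axial compression load-displacement curve
#'
#' A compliant toe region (quadratic ramp-in over `toe_length`) followed by
#' a linear region of slope `stiffness`, truncated at the 1600 N ramp limit
#' used for cadaveric testing, with additive Gaussian load noise.
#'
#' @param stiffness linear-region slope, N/mm (> 0).
#' @param toe_length toe region length, mm (0 = no toe).
#' @param noise_sd load noise standard deviation, N.
#' @param n_points number of samples (>= 21, so a 20-point gradient window
#'   fits).
#' @param seed RNG seed.
#' @param max_load ramp limit, N.
#' @return data.frame with columns `displacement_mm`, `load_N`.
#' @export
simulate_load_curve <- function(stiffness, toe_length = 0.05, noise_sd = 2,
                                n_points = 200, seed = 1L, max_load = 1600) {
  stopifnot(stiffness > 0, toe_length >= 0, noise_sd >= 0)
  if (n_points < 21L)
    stop("n_points must be >= 21 (a 20-segment gradient window must fit)")
  set.seed(seed)
  d_max <- toe_length / 2 + max_load / stiffness
  d <- seq(0, d_max, length.out = n_points)
  load <- ifelse(toe_length > 0 & d <= toe_length,
                 stiffness * d^2 / (2 * toe_length),
                 stiffness * (d - toe_length / 2))
  if (noise_sd > 0) load <- load + stats::rnorm(n_points, 0, noise_sd)
  load <- pmin(pmax(load, 0), max_load)
  data.frame(displacement_mm = d, load_N = load)
}

#' Write/read a specimen record as a directory
#'
#' Volumes are stored as MetaImage, scalars and landmarks as JSON.
#'
#' @param rec a `specimen_record`.
#' @param dir output directory (created if needed).
#' @export
write_specimen <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- c("pre_image", "post_image", "true_bone_mask_pre",
            "interior_mask_pre", "true_cement_mask", "true_needle_mask",
            "true_cement_mask_pre", "true_needle_mask_pre")
  for (v in vols)
    if (!is.null(rec[[v]]))
      write_metaimage(rec[[v]], file.path(dir, paste0(v, ".mhd")))
  write_metaimage(rec$endcap_masks$bottom, file.path(dir, "endcap_bottom.mhd"))
  write_metaimage(rec$endcap_masks$top, file.path(dir, "endcap_top.mhd"))
  if (!is.null(rec$perturbation))
    write_transform(rec$perturbation, file.path(dir, "perturbation.json"))
  meta <- list(load_point = rec$load_point,
               experimental_stiffness = rec$experimental_stiffness,
               render_threshold = rec$render_threshold,
               measured_bvtv = rec$measured_bvtv,
               achieved_fill = rec$achieved_fill,
               landmarks_pre = rec$landmarks_pre,
               landmarks_post = rec$landmarks_post,
               spec = unclass(rec$spec),
               cement_spec = if (!is.null(rec$cement_spec))
                 unclass(rec$cement_spec))
  jsonlite::write_json(meta, file.path(dir, "specimen.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_specimen
#' @export
read_specimen <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "specimen.json"),
                              simplifyVector = TRUE)
  rd <- function(name) {
    p <- file.path(dir, paste0(name, ".mhd"))
    if (file.exists(p)) read_metaimage(p) else NULL
  }
  lm <- function(x) if (!is.null(x)) {
    m <- as.matrix(x); storage.mode(m) <- "double"; m
  }
  rec <- list(pre_image = rd("pre_image"), post_image = rd("post_image"),
              landmarks_pre = lm(meta$landmarks_pre),
              landmarks_post = lm(meta$landmarks_post),
              load_point = meta$load_point,
              experimental_stiffness = meta$experimental_stiffness %||%
                NA_real_,
              true_bone_mask_pre = rd("true_bone_mask_pre"),
              interior_mask_pre = rd("interior_mask_pre"),
              endcap_masks = list(bottom = rd("endcap_bottom"),
                                  top = rd("endcap_top")),
              true_cement_mask = rd("true_cement_mask"),
              true_needle_mask = rd("true_needle_mask"),
              true_cement_mask_pre = rd("true_cement_mask_pre"),
              true_needle_mask_pre = rd("true_needle_mask_pre"),
              perturbation = if (file.exists(file.path(dir, "perturbation.json")))
                read_transform(file.path(dir, "perturbation.json")),
              render_threshold = meta$render_threshold,
              measured_bvtv = meta$measured_bvtv,
              achieved_fill = meta$achieved_fill,
              spec = if (!is.null(meta$spec))
                structure(meta$spec, class = "phantom_spec"),
              cement_spec = if (!is.null(meta$cement_spec))
                structure(meta$cement_spec, class = "cement_spec"))
  class(rec) <- "specimen_record"
  rec
}
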