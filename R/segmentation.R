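#' Global threshold segmentation
#'
#' @param img grayscale `voxel_image`.
#' @param t threshold; the mask is `img >= t`.
#' @return binary `voxel_image`.
#' @export
apply_threshold <- function(img, t) {
  stopifnot(is_voxel_image(img), is.numeric(t), length(t) == 1L)
  voxel_image(array(as.numeric(img$data >= t), dim(img$data)),
              img$spacing, img$origin)
}

#' Connectivity of a binary structure
#'
#' Returns `Conn = 1 - chi`, where `chi` is the 3-D Euler characteristic of
#' the union of closed voxel cubes (26-connected foreground), computed by
#' counting the vertices, edges, faces and cells of the cubical complex:
#' `chi = V - E + F - C`. A contractible solid has `chi = 1` (Conn 0); each
#' independent handle (as in a trabecular network) raises Conn by one; each
#' extra disconnected piece lowers it by one. Conn is the quantity maximised
#' by connectivity-based threshold selection for trabecular bone.
#'
#' @param mask binary `voxel_image`.
#' @return single number `1 - chi`.
#' @export
connectivity <- function(mask) {
  stopifnot(is_voxel_image(mask))
  assert_binary(mask)
  1 - euler_characteristic(mask$data > 0)
}

euler_characteristic <- function(m) {
  d <- dim(m)
  P <- array(FALSE, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  vx <- seq_len(d[1] + 1L); vy <- seq_len(d[2] + 1L); vz <- seq_len(d[3] + 1L)
  cx <- 2:(d[1] + 1L);      cy <- 2:(d[2] + 1L);      cz <- 2:(d[3] + 1L)
  or_over <- function(xs, ys, zs) {
    # OR of P over all index-shift combinations given as lists
    acc <- NULL
    for (sx in xs) for (sy in ys) for (sz in zs) {
      blk <- P[sx, sy, sz]
      acc <- if (is.null(acc)) blk else acc | blk
    }
    sum(acc)
  }
  s01 <- function(v) list(v, v + 1L)
  V <- or_over(s01(vx), s01(vy), s01(vz))
  E <- or_over(list(cx), s01(vy), s01(vz)) +
       or_over(s01(vx), list(cy), s01(vz)) +
       or_over(s01(vx), s01(vy), list(cz))
  Fc <- or_over(s01(vx), list(cy), list(cz)) +
        or_over(list(cx), s01(vy), list(cz)) +
        or_over(list(cx), list(cy), s01(vz))
  C <- sum(m)
  V - E + Fc - C
}

#' Connectivity-maximising threshold selection
#'
#' Sweeps a grayscale threshold grid, computes the connectivity of the
#' resulting trabecular mask at each value and selects the threshold that
#' maximises connectivity (ties broken by the lowest threshold). The full
#' scan is returned for inspection.
#'
#' @param img grayscale `voxel_image`.
#' @param t_range length-2 numeric, inclusive sweep bounds.
#' @param t_step grid step.
#' @return object of class `threshold_scan`: list with `thresholds`,
#'   `connectivity` and `selected`.
#' @export
optimize_threshold <- function(img, t_range, t_step = 1) {
  stopifnot(is_voxel_image(img), length(t_range) == 2L, t_step > 0)
  if (t_range[2] < t_range[1]) stop("empty threshold range")
  thresholds <- t_range[1] + t_step * (0:floor((t_range[2] - t_range[1]) / t_step))
  conn <- vapply(thresholds,
                 function(t) connectivity(apply_threshold(img, t)),
                 numeric(1))
  structure(list(thresholds = thresholds, connectivity = conn,
                 selected = thresholds[which.max(conn)]),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %d thresholds in [%g, %g], selected %g (Conn = %g)\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              x$selected, max(x$connectivity)))
  invisible(x)
}

#' Write a threshold scan as CSV
#' @param scan a `threshold_scan`.
#' @param path CSV path.
#' @export
write_threshold_scan <- function(scan, path) {
  utils::write.csv(
    data.frame(threshold = scan$thresholds, connectivity = scan$connectivity,
               selected = scan$thresholds == scan$selected),
    path, row.names = FALSE)
  invisible(path)
}

#' Cohort threshold: mean of per-specimen selections
#'
#' The segmentation threshold applied to every specimen is the arithmetic
#' mean of the per-specimen connectivity-optimal thresholds.
#'
#' @param scans list of `threshold_scan` objects (length >= 1).
#' @return single grayscale value.
#' @export
cohort_threshold <- function(scans) {
  if (length(scans) == 0L) stop("at least one threshold scan is required")
  mean(vapply(scans, function(s) s$selected, numeric(1)))
}

coarse_factor <- function(fine_spacing, coarse_spacing) {
  f <- coarse_spacing / fine_spacing
  if (abs(f - round(f)) > 1e-6 * f)
    stop("coarse spacing must be an integer multiple of fine spacing")
  as.integer(round(f))
}

#' Bone-volume-fraction field
#'
#' Binarised fine-resolution bone downsampled by block means, so each coarse
#' voxel value equals the local BV/TV in \[0, 1\]. Bone volume is conserved
#' exactly (up to float rounding).
#'
#' @param bone_mask binary fine-resolution `voxel_image`.
#' @param coarse_spacing target spacing (mm), an integer multiple of the
#'   fine spacing.
#' @return fraction-field `voxel_image` at the coarse spacing.
#' @export
bvtv_field <- function(bone_mask, coarse_spacing) {
  stopifnot(is_voxel_image(bone_mask))
  assert_binary(bone_mask, "bone_mask")
  block_downsample(bone_mask, coarse_factor(bone_mask$spacing, coarse_spacing))
}

#' Direct-grayscale field
#'
#' Raw grayscale downsampled by block means and mapped to \[0, 1\] by
#' dividing by 255. Marrow and other soft-tissue intensity deliberately
#' remains in this field (it is the defining difference from [bvtv_field]).
#'
#' @param img grayscale `voxel_image` in \[0, 255\].
#' @inheritParams bvtv_field
#' @return fraction-field `voxel_image`.
#' @export
grayscale_field <- function(img, coarse_spacing) {
  stopifnot(is_voxel_image(img))
  out <- block_downsample(img, coarse_factor(img$spacing, coarse_spacing))
  out$data <- out$data / 255
  out
}

#' Label 26-connected components of a binary array
#'
#' @param m logical or 0/1 3-D array.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in decreasing size order.
#' @export
label_components <- function(m) {
  m <- m > 0
  lab <- array(0L, dim(m))
  remaining <- m
  sizes <- integer(0)
  nl <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(m))
    seed[which(remaining)[1L]] <- TRUE
    comp <- seed
    repeat {
      grown <- dilate_once(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    nl <- nl + 1L
    lab[comp] <- nl
    sizes[nl] <- sum(comp)
    remaining <- remaining & !comp
  }
  if (nl > 1L) {
    ord <- order(sizes, decreasing = TRUE)
    relabel <- integer(nl)
    relabel[ord] <- seq_len(nl)
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
  }
  lab
}

#' Body mask from a fraction field
#'
#' Thresholds the field at `floor` and keeps only the largest 26-connected
#' component, so floating debris never enters the mesh.
#'
#' @param field fraction-field `voxel_image`.
#' @param floor minimum field value counted as body.
#' @return binary `voxel_image`.
#' @export
body_mask_from_field <- function(field, floor) {
  stopifnot(is_voxel_image(field))
  m <- field$data >= floor
  if (!any(m)) stop("body mask is empty at the given floor")
  lab <- label_components(m)
  voxel_image(array(as.numeric(lab == 1L), dim(m)), field$spacing,
              field$origin)
}

#' Remove small components from a binary mask
#'
#' @param mask binary `voxel_image`.
#' @param min_voxels components smaller than this are dropped.
#' @return binary `voxel_image`.
#' @export
remove_small_components <- function(mask, min_voxels) {
  stopifnot(is_voxel_image(mask))
  assert_binary(mask)
  if (min_voxels <= 1L || !any(mask$data > 0)) return(mask)
  lab <- label_components(mask$data)
  keep <- which(tabulate(lab[lab > 0L]) >= min_voxels)
  voxel_image(array(as.numeric(lab %in% keep & lab > 0L), dim(lab)),
              mask$spacing, mask$origin)
}
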