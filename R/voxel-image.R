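#' Voxel image: 3-D scalar grid with physical spacing and origin
#'
#' The shared carrier for grayscale scans (values in \[0, 255\]), binary
#' masks (\{0, 1\}) and fraction fields (\[0, 1\]). Voxels are cubes with
#' isotropic edge length `spacing` (mm); the physical coordinate of the
#' centre of voxel `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`.
#'
#' @param data numeric 3-D array.
#' @param spacing isotropic voxel edge length in mm (> 0).
#' @param origin physical position (mm) of the centre of voxel (0,0,0).
#' @return An object of class `voxel_image` with fields `data`, `spacing`,
#'   `origin`.
#' @export
voxel_image <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive number (mm)")
  if (length(origin) != 3L || !is.numeric(origin))
    stop("`origin` must be a length-3 numeric vector (mm)")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, spacing %g mm\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  origin (%g, %g, %g) mm, value range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

is_voxel_image <- function(x) inherits(x, "voxel_image")

#' Grid geometry without the data
#'
#' @param shape integer voxel counts per axis.
#' @param spacing voxel edge length, mm.
#' @param origin centre of voxel (0,0,0), mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), spacing > 0,
            length(origin) == 3L)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "grid_spec")
}

#' @rdname grid_spec
#' @param img a `voxel_image`.
#' @export
grid_of <- function(img) {
  stopifnot(is_voxel_image(img))
  grid_spec(dim(img$data), img$spacing, img$origin)
}

assert_binary <- function(img, what = "mask") {
  v <- img$data
  if (!all(v == 0 | v == 1))
    stop(sprintf("%s must be binary (values in {0, 1})", what))
  invisible(TRUE)
}

#' Physical coordinates of all voxel centres
#'
#' @param g a `grid_spec` or `voxel_image`.
#' @return n x 3 matrix of mm coordinates in array (column-major) order.
#' @keywords internal
voxel_centres <- function(g) {
  if (is_voxel_image(g)) g <- grid_of(g)
  d <- g$shape
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  cbind(g$origin[1] + i * g$spacing,
        g$origin[2] + j * g$spacing,
        g$origin[3] + k * g$spacing)
}

#' Block-mean downsampling
#'
#' Each output voxel is the arithmetic mean of its `factor^3` source block,
#' so total intensity is conserved: `sum(out) * factor^3 == sum(padded in)`.
#' Dimensions not divisible by `factor` are zero-padded at the high-index
#' end; the pad is recorded in attribute `"pad"` of the result.
#'
#' Applied to a binary bone mask this yields the local bone volume fraction
#' (BV/TV) of each coarse voxel; applied to a grayscale scan it yields the
#' downsampled background used by the direct-grayscale material route.
#'
#' @param img a `voxel_image`.
#' @param factor integer downsampling factor (>= 1).
#' @return `voxel_image` with spacing `factor * img$spacing`. The origin is
#'   shifted so coarse voxel centres sit at the centre of their source block.
#' @export
block_downsample <- function(img, factor) {
  stopifnot(is_voxel_image(img))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be an integer >= 1")
  x <- img$data
  d <- dim(x)
  if (factor == 1L) {
    out <- voxel_image(x, img$spacing, img$origin)
    attr(out, "pad") <- c(0L, 0L, 0L)
    return(out)
  }
  pad <- (factor - d %% factor) %% factor
  if (any(pad > 0L)) {
    xp <- array(0, d + pad)
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    x <- xp
    d <- dim(x)
  }
  dc <- d %/% factor
  dim(x) <- c(factor, dc[1], factor, dc[2], factor, dc[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(factor^3, prod(dc))
  out <- array(colMeans(x), dc)
  # coarse voxel (0,0,0) spans fine voxels 0..factor-1; its centre sits at
  # origin + (factor-1)/2 * spacing
  new_origin <- img$origin + (factor - 1) / 2 * img$spacing
  res <- voxel_image(out, img$spacing * factor, new_origin)
  attr(res, "pad") <- as.integer(pad)
  res
}

# one 26-connected (3x3x3 cube) dilation step on a padded logical array
dilate_once <- function(m) {
  d <- dim(m)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  out <- array(FALSE, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    out <- out | p[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])]
  }
  out
}

#' Morphological dilation of a binary mask
#'
#' Applies a 26-connected cubic (3 x 3 x 3) structuring element
#' `radius_voxels` times, i.e. grows the mask by `radius_voxels` in
#' Chebyshev distance. Dilation is extensive (`mask` is a subset of the
#' result) and monotone.
#'
#' @param mask binary `voxel_image`.
#' @param radius_voxels non-negative integer number of dilation passes.
#' @return binary `voxel_image` on the same grid.
#' @export
dilate_mask <- function(mask, radius_voxels) {
  stopifnot(is_voxel_image(mask))
  assert_binary(mask)
  radius_voxels <- as.integer(radius_voxels)
  if (is.na(radius_voxels) || radius_voxels < 0L)
    stop("`radius_voxels` must be a non-negative integer")
  m <- mask$data > 0
  r <- radius_voxels
  while (r > 0L) {
    m <- dilate_once(m)
    r <- r - 1L
  }
  voxel_image(array(as.numeric(m), dim(m)), mask$spacing, mask$origin)
}

#' Nearest-neighbour resampling under a rigid transform
#'
#' Fills each voxel of `target` with the value of the nearest source voxel:
#' the target voxel centre is mapped through the inverse of `transform`
#' (which maps source physical coordinates onto target physical
#' coordinates) and rounded to the nearest source index. Coordinates
#' falling outside the source domain yield 0.
#'
#' @param img source `voxel_image`.
#' @param transform `rigid_transform` mapping source space to target space.
#' @param target `grid_spec` (or `voxel_image` whose grid is used).
#' @return `voxel_image` on the target grid.
#' @export
resample_nearest <- function(img, transform, target) {
  stopifnot(is_voxel_image(img))
  if (is_voxel_image(target)) target <- grid_of(target)
  stopifnot(inherits(target, "grid_spec"))
  pts <- voxel_centres(target)                       # target physical coords
  src <- apply_transform(invert_transform(transform), pts)
  idx <- round(sweep(src, 2, img$origin) / img$spacing)
  d <- dim(img$data)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
        idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- numeric(nrow(idx))
  lin <- 1L + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])
  out[ok] <- img$data[lin]
  voxel_image(array(out, target$shape), target$spacing, target$origin)
}
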