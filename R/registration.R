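#' Segment cement from a post-augmentation scan
#'
#' High-intensity thresholding at the fine scan resolution followed by
#' small-component removal. Segmenting at fine resolution, before any
#' downsampling, keeps the cement boundary sharp; the result is converted
#' to coarse element classes later by majority-occupancy voting.
#'
#' @param post_img post-augmentation grayscale `voxel_image`.
#' @param cement_threshold grayscale threshold; cement = `>= threshold`.
#' @param min_component_voxels components smaller than this are removed
#'   (barium-sulfate speckle and noise).
#' @return binary fine-resolution `voxel_image`. An empty result (e.g. a
#'   non-augmented control) is valid and raised as a warning only.
#' @export
segment_cement <- function(post_img, cement_threshold,
                           min_component_voxels = 27L) {
  stopifnot(is_voxel_image(post_img))
  mask <- apply_threshold(post_img, cement_threshold)
  mask <- remove_small_components(mask, min_component_voxels)
  if (!any(mask$data > 0))
    warning("cement segmentation is empty (non-augmented scan?)")
  mask
}

#' Composite material layout of an augmented vertebra
#'
#' Combines the bone field of the pre-augmentation scan with the cement
#' (and optionally needle-track) masks of the post-augmentation scan,
#' brought into the pre-augmentation frame by a rigid transform. Using the
#' pre-augmentation bone field avoids the bright cement halo corrupting the
#' bone material map. Class precedence is cement > interface > needle >
#' bone; the interface is a one-coarse-voxel (1 mm) dilation shell around
#' the cement, restricted to the body.
#'
#' @param pre_field coarse fraction-field `voxel_image` from the
#'   pre-augmentation scan (BV/TV or grayscale route).
#' @param body_mask coarse binary body mask on the same grid.
#' @param cement_mask_fine fine binary cement mask in post-scan space (or
#'   already in pre space when `transform` is `NULL` and the grids match).
#' @param transform `rigid_transform` mapping post space onto pre space,
#'   or `NULL` for identity.
#' @param needle_mask_fine optional fine binary needle-track mask, post
#'   space.
#' @param interface_thickness_voxels interface shell thickness in coarse
#'   voxels (default 1 = 1 mm); 0 disables the interface layer.
#' @param fine_grid `grid_spec` of the pre-augmentation fine grid used for
#'   resampling (defaults to the post mask's own grid, which is correct
#'   when pre and post scans share shape and spacing).
#' @return object of class `augmented_layout`: list of coarse
#'   `voxel_image`s `bone_field`, `cement_mask`, `interface_mask`,
#'   `needle_mask`, `body_mask`.
#' @export
build_augmented_layout <- function(pre_field, body_mask, cement_mask_fine,
                                   transform = NULL,
                                   needle_mask_fine = NULL,
                                   interface_thickness_voxels = 1L,
                                   fine_grid = NULL) {
  stopifnot(is_voxel_image(pre_field), is_voxel_image(body_mask))
  assert_binary(body_mask, "body_mask")
  if (!all(dim(pre_field) == dim(body_mask)))
    stop("pre_field and body_mask must share a grid")

  to_coarse <- function(fine_mask) {
    if (is.null(fine_mask)) return(NULL)
    assert_binary(fine_mask, "fine mask")
    m <- fine_mask
    if (!is.null(transform)) {
      tgt <- fine_grid %||% grid_of(fine_mask)
      m <- resample_nearest(m, transform, tgt)
    } else if (!is.null(fine_grid)) {
      if (!all(dim(m) == fine_grid$shape))
        stop("grids differ but no transform was supplied")
    }
    occ <- block_downsample(m, coarse_factor(m$spacing, pre_field$spacing))
    if (!all(dim(occ) == dim(pre_field)))
      stop("coarse grids of the pre field and the resampled mask differ")
    occ$data <- array(as.numeric(occ$data >= 0.5), dim(occ$data))  # majority
    occ$origin <- pre_field$origin
    occ
  }

  cement <- to_coarse(cement_mask_fine)
  if (is.null(cement))
    cement <- voxel_image(array(0, dim(pre_field)), pre_field$spacing,
                          pre_field$origin)
  cement$data <- array(cement$data * body_mask$data, dim(pre_field))

  if (interface_thickness_voxels > 0L && any(cement$data > 0)) {
    dil <- dilate_mask(cement, interface_thickness_voxels)
    iface <- (dil$data > 0) & !(cement$data > 0) & (body_mask$data > 0)
  } else {
    iface <- array(FALSE, dim(pre_field))
  }
  interface_mask <- voxel_image(array(as.numeric(iface), dim(pre_field)),
                                pre_field$spacing, pre_field$origin)

  layout <- structure(list(
    bone_field = pre_field, body_mask = body_mask, cement_mask = cement,
    interface_mask = interface_mask,
    needle_mask = voxel_image(array(0, dim(pre_field)), pre_field$spacing,
                              pre_field$origin)),
    class = "augmented_layout")
  if (!is.null(needle_mask_fine)) {
    needle_coarse <- to_coarse(needle_mask_fine)
    layout <- carve_needle_track(layout, needle_coarse = needle_coarse)
  }
  layout
}

#' Carve the needle track into an augmented layout
#'
#' Coarse voxels with majority needle occupancy that are not cement (and
#' not interface) are reclassified as needle: they are retained in the mesh
#' but carry the void-floor material, representing trabeculae destroyed by
#' the cannula.
#'
#' @param layout an `augmented_layout`.
#' @param needle_mask_fine fine binary needle mask (post space).
#' @param transform `rigid_transform` post -> pre, or `NULL`.
#' @param needle_coarse already-coarse binary needle mask (used internally;
#'   supply either this or `needle_mask_fine`).
#' @inheritParams build_augmented_layout
#' @return the updated `augmented_layout`.
#' @export
carve_needle_track <- function(layout, needle_mask_fine = NULL,
                               transform = NULL, fine_grid = NULL,
                               needle_coarse = NULL) {
  stopifnot(inherits(layout, "augmented_layout"))
  pf <- layout$bone_field
  if (is.null(needle_coarse)) {
    if (is.null(needle_mask_fine)) return(layout)
    m <- needle_mask_fine
    assert_binary(m, "needle mask")
    if (!is.null(transform))
      m <- resample_nearest(m, transform, fine_grid %||% grid_of(m))
    occ <- block_downsample(m, coarse_factor(m$spacing, pf$spacing))
    occ$data <- array(as.numeric(occ$data >= 0.5), dim(occ$data))
    occ$origin <- pf$origin
    needle_coarse <- occ
  }
  ndl <- (needle_coarse$data > 0) & (layout$body_mask$data > 0) &
    !(layout$cement_mask$data > 0) & !(layout$interface_mask$data > 0)
  layout$needle_mask <- voxel_image(array(as.numeric(ndl), dim(pf$data)),
                                    pf$spacing, pf$origin)
  layout
}

#' @export
print.augmented_layout <- function(x, ...) {
  cat(sprintf(
    "<augmented_layout> %s coarse voxels: body %d, cement %d, interface %d, needle %d\n",
    paste(dim(x$bone_field), collapse = " x "),
    sum(x$body_mask$data > 0), sum(x$cement_mask$data > 0),
    sum(x$interface_mask$data > 0), sum(x$needle_mask$data > 0)))
  invisible(x)
}

#' Dice overlap of two binary masks
#'
#' @param a,b binary `voxel_image`s on a common grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  A <- a$data > 0; B <- b$data > 0
  2 * sum(A & B) / (sum(A) + sum(B))
}
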