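# Shared fixtures, built in code and memoised so expensive phantom and FE
# objects are constructed once per test file.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# small phantom: ~50 x 40 x 60 fine voxels, ~1.1k coarse elements
tiny_phantom_spec <- function(seed = 1L, bvtv = 0.2, ...) {
  phantom_spec(body_semiaxes = c(6, 5), body_height = 10,
               endcap_thickness = 2.5, fine_spacing = 0.25,
               strut_period = 1.2, target_bvtv = bvtv, seed = seed, ...)
}

tiny_phantom <- function(seed = 1L, bvtv = 0.2, ...) {
  generate_vertebra_phantom(tiny_phantom_spec(seed = seed, bvtv = bvtv, ...))
}

random_mask_image <- function(dims, p = 0.3, seed = 1L, spacing = 1) {
  set.seed(seed)
  voxel_image(array(as.numeric(stats::runif(prod(dims)) < p), dims), spacing)
}

random_gray_image <- function(dims, seed = 1L, spacing = 1) {
  set.seed(seed)
  voxel_image(array(as.numeric(sample(0:255, prod(dims), TRUE)), dims),
              spacing)
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  rotation_about(ax, stats::runif(1, -40, 40),
                 centre = stats::rnorm(3, 0, 2),
                 translation = stats::rnorm(3, 0, 3))
}

# one augmented tiny phantom shared across files that need it
aug_phantom <- function() {
  fixture("aug_phantom", function() {
    rec <- tiny_phantom(seed = 11, bvtv = 0.22)
    inject_cement(rec, cement_spec("concentrated", fill_fraction = 0.25))
  })
}

aug_model <- function() {
  fixture("aug_model", function() {
    rec <- aug_phantom()
    cfg <- pipeline_config()
    vertebrofe:::build_specimen_model(rec, 105, cfg)
  })
}
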