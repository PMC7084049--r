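test_that("voxel_image enforces its invariants", {
  expect_error(voxel_image(matrix(0, 2, 2), 1), "3-D")
  expect_error(voxel_image(array(0, c(2, 2, 2)), -1), "positive")
  img <- voxel_image(array(1, c(2, 3, 4)), 0.082, c(1, 2, 3))
  expect_identical(dim(img), c(2L, 3L, 4L))
  expect_equal(img$spacing, 0.082)
})

test_that("TIFF volume round-trip preserves 8-bit data exactly", {
  set.seed(5)
  arr <- array(as.numeric(sample(0:255, 4 * 4 * 4, TRUE)), c(4, 4, 4))
  img <- voxel_image(arr, 0.082)
  path <- file.path(tempdir(), "vol.tif")
  write_volume_tiff(img, path)
  back <- read_volume(path)
  expect_identical(back$data, arr)
  expect_equal(back$spacing, 0.082)
})

test_that("MetaImage round-trip preserves data, spacing and origin", {
  set.seed(6)
  arr <- array(stats::runif(60), c(3, 4, 5))
  img <- voxel_image(arr, 0.082, c(-1, 0.5, 2))
  path <- file.path(tempdir(), "vol.mhd")
  write_metaimage(img, path)
  back <- read_volume(path)
  expect_equal(back$data, arr)
  expect_equal(back$spacing, 0.082)
  expect_equal(back$origin, c(-1, 0.5, 2))
})

test_that("malformed stacks and unsupported depths fail loudly", {
  d <- file.path(tempdir(), "badstack")
  dir.create(d, showWarnings = FALSE)
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(d, "s1.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(matrix(0.5, 4, 6), file.path(d, "s2.tif"),
                  bits.per.sample = 8L)
  expect_error(read_volume(d), "inconsistent slice dimensions")
  expect_error(read_volume(file.path(tempdir(), "nope.tif")), "no such file")
})

test_that("block_downsample is an exact block mean and conserves intensity", {
  # constant image stays constant under any factor
  cimg <- voxel_image(array(7, c(6, 6, 6)), 1)
  expect_true(all(block_downsample(cimg, 3)$data == 7))
  # half-ones block collapses to 0.5
  arr <- array(0, c(2, 2, 2)); arr[1:2, 1:2, 1] <- 1
  expect_equal(block_downsample(voxel_image(arr, 1), 2)$data[1, 1, 1], 0.5)
  # brute-force block mean on a random binary 6^3 volume
  img <- random_mask_image(c(6, 6, 6), 0.5, seed = 2)
  out <- block_downsample(img, 3)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    blk <- img$data[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j),
                    (3 * k - 2):(3 * k)]
    expect_equal(out$data[i, j, k], mean(blk))
  }
  # conservation with zero-padding of non-divisible dimensions
  img2 <- random_gray_image(c(7, 6, 5), seed = 3)
  out2 <- block_downsample(img2, 2)
  expect_equal(sum(out2$data) * 8, sum(img2$data), tolerance = 1e-12)
  expect_identical(attr(out2, "pad"), c(1L, 0L, 1L))
  expect_equal(out2$spacing, 2)
  expect_error(block_downsample(img2, 0), ">= 1")
})

test_that("dilate_mask matches the brute-force Chebyshev-ball definition", {
  empty <- voxel_image(array(0, c(4, 4, 4)), 1)
  expect_true(all(dilate_mask(empty, 2)$data == 0))
  single <- voxel_image(array(0, c(5, 5, 5)), 1)
  single$data[3, 3, 3] <- 1
  expect_equal(sum(dilate_mask(single, 1)$data), 27)
  # random mask, radius 2: set of voxels within Chebyshev distance 2
  mask <- random_mask_image(c(8, 7, 6), 0.1, seed = 4)
  out <- dilate_mask(mask, 2)
  src <- which(mask$data > 0, arr.ind = TRUE)
  d <- dim(mask$data)
  brute <- array(0, d)
  for (v in seq_len(prod(d))) {
    ijk <- arrayInd(v, d)
    cheb <- min(apply(abs(sweep(src, 2, as.vector(ijk))), 1, max))
    brute[v] <- as.numeric(cheb <= 2)
  }
  expect_identical(out$data, brute)
  expect_error(dilate_mask(random_gray_image(c(3, 3, 3)), 1), "binary")
})

test_that("dilation is extensive and monotone", {
  a <- random_mask_image(c(10, 9, 8), 0.15, seed = 7)
  b <- a
  b$data <- pmax(b$data, random_mask_image(c(10, 9, 8), 0.1, seed = 8)$data)
  da <- dilate_mask(a, 1); db <- dilate_mask(b, 1)
  expect_true(all(da$data >= a$data))           # extensive
  expect_true(all(db$data >= da$data))          # monotone (a subset of b)
})

test_that("resample_nearest handles identity, integer shifts and a random
          rigid transform against a brute-force loop", {
  img <- random_gray_image(c(6, 5, 4), seed = 9, spacing = 0.5)
  idt <- rigid_transform()
  expect_identical(resample_nearest(img, idt, grid_of(img))$data, img$data)
  # pure one-voxel translation shifts the image with a zero-filled slab
  tr <- rigid_transform(diag(3), c(0.5, 0, 0))
  sh <- resample_nearest(img, tr, grid_of(img))
  expect_identical(sh$data[2:6, , ], img$data[1:5, , ])
  expect_true(all(sh$data[1, , ] == 0))
  # random rigid transform: per-voxel equality with an explicit loop
  mask <- random_mask_image(c(7, 6, 5), 0.4, seed = 10, spacing = 0.7)
  tr2 <- random_rigid(11)
  out <- resample_nearest(mask, tr2, grid_of(mask))
  inv <- invert_transform(tr2)
  d <- dim(mask$data)
  for (v in sample(prod(d), 100)) {
    ijk <- arrayInd(v, d) - 1L
    pt <- mask$origin + as.vector(ijk) * mask$spacing
    sp <- apply_transform(inv, pt)
    sidx <- round((sp - mask$origin) / mask$spacing)
    expected <- if (all(sidx >= 0) && all(sidx < d))
      mask$data[sidx[1] + 1, sidx[2] + 1, sidx[3] + 1] else 0
    expect_identical(out$data[v], expected)
  }
})
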