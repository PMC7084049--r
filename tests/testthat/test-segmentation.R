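test_that("apply_threshold matches a counting oracle", {
  img <- random_gray_image(c(9, 8, 7), seed = 1)
  expect_true(all(apply_threshold(img, 0)$data == 1))
  expect_true(all(apply_threshold(img, 256)$data == 0))
  t <- stats::median(img$data)
  expect_equal(sum(apply_threshold(img, t)$data), sum(img$data >= t))
})

test_that("connectivity equals 1 - chi on hand-computable complexes", {
  solid <- voxel_image(array(1, c(3, 3, 3)), 1)
  expect_equal(connectivity(solid), 0)          # contractible: chi = 1
  ring <- array(0, c(5, 5, 3))                  # square voxel torus
  ring[2:4, 2:4, 2] <- 1; ring[3, 3, 2] <- 0
  expect_equal(connectivity(voxel_image(ring, 1)), 1)  # one handle: chi = 0
  two <- array(0, c(7, 3, 3)); two[1:3, , ] <- 1; two[5:7, , ] <- 1
  expect_equal(connectivity(voxel_image(two, 1)), -1)  # chi additive: 2
})

test_that("connectivity is additive over well-separated components", {
  set.seed(21)
  a <- array(0, c(16, 8, 8))
  a[1:6, 2:7, 2:7] <- stats::runif(6 * 6 * 6) < 0.5
  b <- array(0, c(16, 8, 8))
  b[10:15, 2:7, 2:7] <- stats::runif(6 * 6 * 6) < 0.5
  ca <- connectivity(voxel_image(a, 1))
  cb <- connectivity(voxel_image(b, 1))
  cab <- connectivity(voxel_image(pmax(a, b), 1))
  # chi(A u B) = chi(A) + chi(B) => Conn(A u B) = Conn(A) + Conn(B) - 1
  expect_equal(cab, ca + cb - 1)
})

test_that("optimize_threshold sweeps exhaustively and breaks ties low", {
  # two-level image: any threshold strictly between levels gives the same
  # mask, so the scan plateaus and the lowest grid point wins
  img <- voxel_image(array(c(50, 200)[1 + (random_mask_image(
    c(10, 10, 10), 0.3, seed = 3)$data)], c(10, 10, 10)), 1)
  scan <- optimize_threshold(img, c(60, 190), 10)
  expect_length(scan$thresholds, floor((190 - 60) / 10) + 1)
  expect_equal(scan$selected, 60)
  conns <- scan$connectivity
  expect_true(all(conns == conns[1]))
  expect_error(optimize_threshold(img, c(100, 90), 10), "empty")
})

test_that("selected threshold on a rendered phantom separates marrow from
          bone", {
  rec <- fixture("seg_phantom", function() tiny_phantom(seed = 31))
  cfg <- pipeline_config()
  scan <- vertebrofe:::specimen_threshold_scan(rec, cfg)
  sp <- rec$spec
  expect_gt(scan$selected, sp$marrow_level)
  expect_lt(scan$selected, sp$bone_level)
  # the mask at the selected threshold recovers the true trabecular network:
  # it must overlap the ground-truth bone strongly
  mask <- apply_threshold(rec$pre_image, scan$selected)
  caps <- (rec$endcap_masks$bottom$data > 0) | (rec$endcap_masks$top$data > 0)
  mask$data[caps] <- 0
  expect_gt(dice_overlap(mask, rec$true_bone_mask_pre), 0.5)
})

test_that("cohort_threshold is the arithmetic mean of selections", {
  mk <- function(sel) structure(list(selected = sel), class = "threshold_scan")
  expect_equal(cohort_threshold(list(mk(120))), 120)
  expect_equal(cohort_threshold(list(mk(100), mk(120))), 110)
  set.seed(9); v <- sample(50:200, 7)
  expect_equal(cohort_threshold(lapply(v, mk)), mean(v))
  expect_error(cohort_threshold(list()), "at least one")
})

test_that("bvtv_field conserves bone volume exactly", {
  solid <- voxel_image(array(1, c(8, 8, 8)), 0.25)
  expect_true(all(bvtv_field(solid, 1)$data == 1))
  half <- voxel_image(array(rep(c(1, 0), 4 * 8 * 8), c(8, 8, 8)), 0.5)
  expect_true(all(abs(bvtv_field(half, 1)$data - 0.5) < 1e-15))
  rec <- fixture("seg_phantom", function() tiny_phantom(seed = 31))
  f <- bvtv_field(rec$true_bone_mask_pre, 1)
  fac <- as.integer(round(1 / rec$pre_image$spacing))
  expect_equal(sum(f$data) * fac^3, sum(rec$true_bone_mask_pre$data),
               tolerance = 1e-12)
  expect_error(bvtv_field(solid, 0.9), "integer multiple")
})

test_that("grayscale_field is the block mean scaled to [0, 1]", {
  c255 <- voxel_image(array(255, c(4, 4, 4)), 0.5)
  expect_true(all(grayscale_field(c255, 1)$data == 1))
  c0 <- voxel_image(array(0, c(4, 4, 4)), 0.5)
  expect_true(all(grayscale_field(c0, 1)$data == 0))
  img <- random_gray_image(c(4, 4, 4), seed = 12, spacing = 0.5)
  gf <- grayscale_field(img, 1)
  expect_equal(gf$data[1, 1, 1], mean(img$data[1:2, 1:2, 1:2]) / 255)
  expect_equal(gf$data[2, 2, 2], mean(img$data[3:4, 3:4, 3:4]) / 255)
})

test_that("body_mask_from_field keeps only the largest component", {
  f <- voxel_image(array(0, c(12, 6, 6)), 1)
  f$data[1:5, 2:5, 2:5] <- 0.8          # 80-voxel block
  f$data[10, 3, 3] <- 0.9               # 1-voxel debris
  m <- body_mask_from_field(f, 0.5)
  expect_equal(sum(m$data), 80)
  expect_equal(max(m$data[10, , ]), 0)
  all_m <- body_mask_from_field(voxel_image(array(0.2, c(3, 3, 3)), 1), 0)
  expect_true(all(all_m$data == 1))
  expect_error(body_mask_from_field(f, 2), "empty")
})

test_that("remove_small_components drops exactly the sub-threshold blobs", {
  m <- voxel_image(array(0, c(14, 6, 6)), 1)
  m$data[1:3, 1:3, 1:3] <- 1            # 27 voxels
  m$data[6:7, 1:2, 1:2] <- 1            # 8 voxels
  m$data[11, 1, 1] <- 1                 # 1 voxel
  out <- remove_small_components(m, 8L)
  expect_equal(sum(out$data), 35)
  out2 <- remove_small_components(m, 9L)
  expect_equal(sum(out2$data), 27)
})
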