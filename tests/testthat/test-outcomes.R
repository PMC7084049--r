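brute_window_slope <- function(curve, window = 20L) {
  n <- nrow(curve)
  best <- -Inf
  for (i in 1:(n - window + 1)) {
    seg <- curve[i:(i + window - 1), ]
    best <- max(best, stats::coef(stats::lm(load_N ~ displacement_mm,
                                            seg))[2])
  }
  unname(best)
}

test_that("extract_stiffness returns the maximum 20-point OLS gradient", {
  lin <- simulate_load_curve(1234, toe_length = 0, noise_sd = 0,
                             n_points = 60, seed = 1)
  expect_equal(extract_stiffness(lin), 1234, tolerance = 1e-12)
  # bilinear curve: steep limb slope wins
  d <- seq(0, 1, length.out = 60)
  bil <- data.frame(displacement_mm = d,
                    load_N = ifelse(d < 0.5, 100 * d, 50 + 900 * (d - 0.5)))
  expect_equal(extract_stiffness(bil), 900, tolerance = 1e-9)
  # noisy curve equals the brute-force window sweep
  for (seed in 1:3) {
    cv <- simulate_load_curve(1500, toe_length = 0.08, noise_sd = 6,
                              n_points = 80, seed = seed)
    expect_equal(extract_stiffness(cv), brute_window_slope(cv),
                 tolerance = 1e-9)
  }
  expect_error(extract_stiffness(lin[1:10, ]), "window")
  flat <- data.frame(displacement_mm = rep(0, 25), load_N = 1:25)
  expect_error(extract_stiffness(flat), "zero displacement")
})

test_that("extract_stiffness ignores prepended toe points", {
  base <- simulate_load_curve(2000, toe_length = 0, noise_sd = 0,
                              n_points = 40, seed = 2)
  toe <- data.frame(displacement_mm = seq(-0.2, -0.01, length.out = 15),
                    load_N = seq(0, 5, length.out = 15))
  toe$displacement_mm <- toe$displacement_mm + 0.2
  base$displacement_mm <- base$displacement_mm + 0.2
  both <- rbind(toe, base)
  expect_equal(extract_stiffness(both), extract_stiffness(base),
               tolerance = 1e-9)
})

test_that("ccc matches hand computations and an independent formula", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  brute_ccc <- function(x, y) {
    n <- length(x)
    sxy <- sum((x - mean(x)) * (y - mean(y))) / n
    sx <- sum((x - mean(x))^2) / n
    sy <- sum((y - mean(y))^2) / n
    2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
  }
  set.seed(77)
  for (i in 1:20) {
    x <- stats::rnorm(10); y <- 0.5 * x + stats::rnorm(10)
    expect_equal(ccc(x, y), brute_ccc(x, y), tolerance = 1e-12)
  }
  expect_equal(ccc(rep(2, 5), rep(2, 5)), 1)
  expect_equal(ccc(rep(2, 5), rep(3, 5)), 0)
  expect_error(ccc(1:3, 1:4), "equal length")
})

test_that("|ccc| never exceeds |pearson| and they agree when moments match", {
  set.seed(42)
  for (i in 1:30) {
    x <- stats::rnorm(12, sd = stats::runif(1, 0.5, 2))
    y <- stats::rnorm(12, mean = stats::runif(1, -1, 1))
    expect_lte(abs(ccc(x, y)), abs(stats::cor(x, y)) + 1e-12)
  }
  x <- stats::rnorm(50)
  y <- x[sample(50)]               # same mean and variance
  expect_equal(ccc(x, y), stats::cor(x, y) *
                 1, tolerance = 1e-9)
})

test_that("multiplicative noise on the experimental values lowers ccc in
          expectation", {
  set.seed(9)
  truth <- stats::runif(8, 800, 3000)
  mean_ccc <- function(cv) {
    mean(vapply(1:60, function(s) {
      set.seed(1000 + s)
      ccc(truth, truth * (1 + stats::rnorm(8, 0, cv)))
    }, numeric(1)))
  }
  m <- c(mean_ccc(0.02), mean_ccc(0.08), mean_ccc(0.2))
  expect_true(all(diff(m) < 0))
})

test_that("rms_percent_error matches its definition", {
  expect_equal(rms_percent_error(c(5, 5), c(5, 5)), 0)
  expect_equal(rms_percent_error(1.1 * 7, 7), 10, tolerance = 1e-12)
  set.seed(3)
  p <- stats::runif(9, 1, 2); e <- stats::runif(9, 1, 2)
  expect_equal(rms_percent_error(p, e),
               sqrt(mean(((p - e) / e)^2)) * 100, tolerance = 1e-12)
  expect_error(rms_percent_error(1, 0), "positive")
})

test_that("split_specimens is an even, seeded, disjoint partition", {
  ids <- sprintf("v%02d", 1:14)
  sp <- split_specimens(ids, seed = 4)
  expect_length(sp$build_ids, 7)
  expect_length(sp$validation_ids, 7)
  expect_setequal(c(sp$build_ids, sp$validation_ids), ids)
  expect_length(intersect(sp$build_ids, sp$validation_ids), 0)
  expect_identical(split_specimens(ids, seed = 4), sp)
  expect_false(identical(split_specimens(ids, seed = 5), sp))
  odd <- split_specimens(1:7, seed = 1)
  expect_equal(abs(length(odd$build_ids) - length(odd$validation_ids)), 1)
  expect_error(split_specimens("a"), "at least two")
})

test_that("calibration recovers the generating factor on noiseless synthetic
          columns and respects its bounds", {
  # synthetic specimens: small inhomogeneous columns with platen-free
  # uniaxial BCs, experiments generated at k_true
  k_true <- 9e-4
  specs <- fixture("cal_columns", function() {
    lapply(1:3, function(s) {
      set.seed(s)
      mesh <- block_mesh(3, 3, 5, edge = 1)
      mesh$element_fraction <- stats::runif(nrow(mesh$elements), 0.1, 1)
      fe_specimen(mesh, uniaxial_bcs(mesh, 1), NA_real_, id = sprintf("c%d", s))
    })
  })
  specs <- lapply(specs, function(sp) {
    fn <- make_stiffness_fn(sp$mesh, sp$bcs)
    sp$experimental_stiffness <- fn(k_true)
    sp
  })
  cal <- calibrate_k(specs, bounds = c(1e-4, 1e-2))
  expect_lt(abs(cal$k_star - k_true) / k_true, 0.01)
  expect_gt(cal$ccc, 0.999)
  expect_false(cal$at_boundary)
  # excluding bounds pins the estimate at the nearest bound, flagged
  cal2 <- calibrate_k(specs, bounds = c(1e-3, 1e-2))
  expect_equal(cal2$k_star, 1e-3)
  expect_true(cal2$at_boundary)
})

test_that("single fully linear specimen admits the closed-form factor", {
  # with uniaxial BCs on a pure bone column the stiffness is linear in k, so
  # k* = k0 * S_exp / S(k0)
  mesh <- block_mesh(2, 2, 4, edge = 1)
  mesh$element_fraction <- rep(0.8, nrow(mesh$elements))
  fn <- make_stiffness_fn(mesh, uniaxial_bcs(mesh, 1))
  S1 <- fn(1e-3)
  target <- 0.7 * S1
  sp <- fe_specimen(mesh, uniaxial_bcs(mesh, 1), target)
  cal <- calibrate_k(list(sp), bounds = c(1e-4, 1e-2), tol_rel = 1e-4)
  expect_equal(cal$k_star, 0.7e-3, tolerance = 3e-3)
})

test_that("validate reports pair counts and self-consistent agreement", {
  specs <- fixture("cal_columns", function() stop("fixture missing"))
  specs <- lapply(specs, function(sp) {
    fn <- make_stiffness_fn(sp$mesh, sp$bcs)
    sp$experimental_stiffness <- fn(9e-4)
    sp
  })
  cal <- calibrate_k(specs, bounds = c(1e-4, 1e-2))
  rep <- validate(cal, specs)
  expect_equal(nrow(rep$pairs), length(specs))
  expect_gt(rep$ccc, 0.999)
  expect_lt(rep$rms_percent_error, 1)
  expect_error(validate(cal, list()), "empty")
})

test_that("stiffness evaluator equals the full reassembled solve", {
  b <- aug_model()
  cards <- default_material_cards()
  fn <- make_stiffness_fn(b$mesh, b$bcs, cards = cards)
  for (k in c(3e-4, 9e-4, 4e-3)) {
    mat <- assign_materials(b$mesh, k, cards)
    S_full <- model_stiffness(
      solve_linear(model_definition(b$mesh, mat, b$bcs)))
    expect_equal(fn(k), S_full, tolerance = 1e-9)
  }
})
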