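test_that("hex8 element matrix is symmetric, rank-deficient by 6 and linear
          in E", {
  K <- hex8_stiffness(1000, 0.3, 1)
  expect_equal(max(abs(K - t(K))), 0)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)
  expect_equal(hex8_stiffness(2000, 0.3, 1), 2 * K, tolerance = 1e-15)
  expect_error(hex8_stiffness(1000, 0.5, 1), "< 0.5")
})

test_that("homogeneous column reproduces E*A/L exactly", {
  mesh <- block_mesh(3, 3, 6, edge = 1)
  mat <- uniform_materials(mesh, 0.2, 0.3)
  res <- solve_linear(model_definition(mesh, mat, uniaxial_bcs(mesh, 0.5)))
  expect_true(res$converged)
  S <- model_stiffness(res, 0.5)
  expect_equal(S, 0.2e3 * 9 / 6, tolerance = 1e-6)
})

test_that("two-layer composite matches the series-spring closed form", {
  mesh <- block_mesh(3, 3, 6, edge = 1)
  mat <- uniform_materials(mesh, 0.2, 0)     # nu = 0: layers decouple
  mat$E_gpa[rep(0:5, each = 9) >= 3] <- 0.05
  S <- model_stiffness(
    solve_linear(model_definition(mesh, mat, uniaxial_bcs(mesh, 1))), 1)
  S_exact <- 1 / (3 / (0.2e3 * 9) + 3 / (0.05e3 * 9))
  expect_equal(S, S_exact, tolerance = 1e-6)
})

test_that("linear patch test: affine boundary data yields constant interior
          stress", {
  mesh <- block_mesh(3, 3, 3, edge = 1)
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -5e-4, 2e-4, 1e-4, 2e-4, 8e-4),
              3, byrow = TRUE)
  uaff <- mesh$nodes %*% t(A)
  rng <- apply(mesh$nodes, 2, range)
  onb <- apply(mesh$nodes, 1, function(p)
    any(abs(p - rng[1, ]) < 1e-9 | abs(p - rng[2, ]) < 1e-9))
  bidx <- which(onb)
  pd <- as.vector(t(cbind(3 * bidx - 2, 3 * bidx - 1, 3 * bidx)))
  res <- solve_linear(model_definition(
    mesh, uniform_materials(mesh, 0.1, 0.25),
    custom_bcs(pd, as.vector(t(uaff[bidx, ])))))
  expect_equal(matrix(res$u, ncol = 3, byrow = TRUE), uaff,
               tolerance = 1e-8, ignore_attr = TRUE)
  vm <- res$element_von_mises
  expect_lt(diff(range(vm)) / mean(vm), 1e-8)
})

test_that("sparse solver agrees with a dense brute-force assembly", {
  set.seed(42)
  mesh <- block_mesh(2, 2, 2, edge = 1)
  E <- stats::runif(8, 0.05, 0.5)
  mat <- uniform_materials(mesh, 0.1, 0.3)
  mat$E_gpa <- E
  bcs <- uniaxial_bcs(mesh, 0.3)
  res <- solve_linear(model_definition(mesh, mat, bcs))
  ndof <- 3 * nrow(mesh$nodes)
  Kd <- matrix(0, ndof, ndof)
  for (e in 1:8) {
    Ke <- hex8_stiffness(E[e] * 1000, 0.3, 1)
    dofs <- integer(24)
    for (a in 1:8)
      dofs[(3 * a - 2):(3 * a)] <-
        (3 * mesh$elements[e, a] - 2):(3 * mesh$elements[e, a])
    Kd[dofs, dofs] <- Kd[dofs, dofs] + Ke
  }
  z <- mesh$nodes[, 3]
  bot <- which(z < min(z) + 1e-9); top <- which(z > max(z) - 1e-9)
  presc <- c(3 * bot, 3 * top, 3 * bcs$pin_a - 2, 3 * bcs$pin_a - 1,
             3 * bcs$pin_b - 1)
  vals <- c(rep(0, length(bot)), rep(-0.3, length(top)), 0, 0, 0)
  freed <- setdiff(seq_len(ndof), presc)
  ud <- numeric(ndof); ud[presc] <- vals
  ud[freed] <- solve(Kd[freed, freed], -Kd[freed, presc] %*% vals)
  expect_equal(res$u, ud, tolerance = 1e-9)
  expect_equal(res$platen_reaction, -sum((Kd %*% ud)[3 * top]),
               tolerance = 1e-9)
})

test_that("global equilibrium holds at the solution", {
  b <- aug_model()
  res <- solve_linear(model_definition(b$mesh,
                                       assign_materials(b$mesh, 9e-4),
                                       b$bcs))
  ftot <- colSums(matrix(res$residual, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(ftot)), 1e-6 * abs(res$platen_reaction))
})

test_that("raising element moduli never lowers elastic stiffness", {
  mesh <- block_mesh(3, 3, 5, edge = 1)
  set.seed(31)
  mat <- uniform_materials(mesh, 0.1, 0.3)
  mat$E_gpa <- stats::runif(nrow(mat), 0.02, 0.3)
  bcs <- uniaxial_bcs(mesh, 1)
  S0 <- model_stiffness(solve_linear(model_definition(mesh, mat, bcs)), 1)
  for (rep in 1:3) {
    mat2 <- mat
    bump <- sample(nrow(mat2), 10)
    mat2$E_gpa[bump] <- mat2$E_gpa[bump] * stats::runif(10, 1, 5)
    S1 <- model_stiffness(solve_linear(model_definition(mesh, mat2, bcs)), 1)
    expect_gte(S1, S0 * (1 - 1e-12))
  }
})

test_that("model stiffness is homogeneous of degree one in all moduli", {
  b <- aug_model()
  cards <- default_material_cards()
  cards$interface$yield_stress <- NULL
  mat <- assign_materials(b$mesh, 9e-4, cards)
  S1 <- model_stiffness(solve_linear(model_definition(b$mesh, mat, b$bcs)))
  mat2 <- mat; mat2$E_gpa <- 3 * mat2$E_gpa
  S3 <- model_stiffness(solve_linear(model_definition(b$mesh, mat2, b$bcs)))
  expect_equal(S3, 3 * S1, tolerance = 1e-8)
  expect_equal(model_stiffness(structure(list(platen_reaction = 1600,
                                              prescribed_displacement = 1,
                                              converged = TRUE),
                                         class = "solve_result")), 1600)
})

test_that("elastoplastic solve reduces to the elastic one without yield", {
  mesh <- block_mesh(2, 2, 3, edge = 1)
  bcs <- uniaxial_bcs(mesh, 0.4)
  mat_el <- uniform_materials(mesh, 0.05, 0.35)
  lin <- solve_linear(model_definition(mesh, mat_el, bcs))
  pl <- solve_elastoplastic(model_definition(mesh, mat_el, bcs))
  expect_equal(pl$platen_reaction, lin$platen_reaction, tolerance = 1e-12)
  mat_inf <- uniform_materials(mesh, 0.05, 0.35, yield_pa = 1e15)
  pl2 <- solve_elastoplastic(model_definition(mesh, mat_inf, bcs))
  expect_equal(pl2$platen_reaction, lin$platen_reaction, tolerance = 1e-8)
})

test_that("a single yielding element plateaus at the configured yield", {
  mesh <- block_mesh(1, 1, 1, edge = 1)
  mat <- uniform_materials(mesh, 0.01, 0.4, yield_pa = 5)
  top <- which(mesh$nodes[, 3] > 0.4)
  bot <- which(mesh$nodes[, 3] < -0.4)
  pd <- c(3 * (1:8) - 2, 3 * (1:8) - 1, 3 * bot, 3 * top)
  pv <- c(rep(0, 16 + length(bot)), rep(-0.001, length(top)))
  bcs <- custom_bcs(pd, pv, reaction_dofs = 3 * top)
  res <- solve_elastoplastic(model_definition(mesh, mat, bcs))
  expect_true(res$converged)
  # von Mises sits on the yield surface to within 0.1%
  expect_equal(unique(res$element_von_mises), 5, tolerance = 1e-3)
  expect_true(all(res$plastic_dissipation >= 0))
  # closed form of the plateau: uniaxial strain keeps the volumetric
  # response elastic; the reaction exceeds the purely volumetric force by
  # exactly the deviatoric yield contribution 2/3 * sigy
  eps <- 0.001
  Kb <- 0.01e3 / (3 * (1 - 2 * 0.4))
  expected <- (Kb * eps + 2 / 3 * 5e-6) * 1      # MPa * area -> N
  expect_equal(res$platen_reaction, expected, tolerance = 1e-3)
})

test_that("halving the increment count barely changes the reaction", {
  b <- aug_model()
  model <- model_definition(b$mesh, assign_materials(b$mesh, 9e-4), b$bcs)
  r10 <- solve_elastoplastic(model, solver_config(n_increments = 10))
  r5 <- solve_elastoplastic(model, solver_config(n_increments = 5))
  expect_lt(abs(r5$platen_reaction - r10$platen_reaction) /
              abs(r10$platen_reaction), 0.005)
  vmI <- r10$element_von_mises[b$mesh$element_class == "interface"]
  expect_true(all(vmI <= 5 * (1 + 1e-3)))
})

test_that("singular systems fail with an explicit message", {
  mesh <- block_mesh(2, 2, 2, edge = 1)
  mat <- uniform_materials(mesh, 0.1, 0.3)
  # constrain a single node only: rigid modes remain
  bcs <- custom_bcs(1:3, rep(0, 3))
  suppressWarnings(   # CHOLMOD also emits its own not-positive-definite note
    expect_error(solve_linear(model_definition(mesh, mat, bcs)), "singular"))
})

test_that("VTK and JSON exports are well-formed", {
  mesh <- block_mesh(2, 2, 2)
  res <- solve_linear(model_definition(mesh, uniform_materials(mesh, 0.1, 0.3),
                                       uniaxial_bcs(mesh, 0.1)))
  vtk <- file.path(tempdir(), "out.vtk")
  write_vtk(mesh, res, vtk)
  txt <- readLines(vtk)
  expect_true(any(grepl("POINTS 27 double", txt)))
  expect_true(any(grepl("CELLS 8 72", txt)))
  js <- file.path(tempdir(), "out.json")
  write_solve_summary(res, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$stiffness_N_per_mm,
               res$platen_reaction / 0.1, tolerance = 1e-12)
})
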