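test_that("block meshes have the expected node and element counts", {
  m <- block_mesh(2, 2, 2, edge = 1)
  expect_equal(nrow(m$elements), 8)
  expect_equal(nrow(m$nodes), 27)
  m2 <- block_mesh(3, 1, 2, edge = 0.5)
  expect_equal(nrow(m2$elements), 6)
  expect_equal(nrow(m2$nodes), 4 * 2 * 3)
})

test_that("mesh is conforming: interior faces shared by exactly 2 elements", {
  m <- aug_model()$mesh
  el <- m$elements
  faces <- rbind(el[, c(1, 2, 3, 4)], el[, c(5, 6, 7, 8)],
                 el[, c(1, 2, 6, 5)], el[, c(2, 3, 7, 6)],
                 el[, c(3, 4, 8, 7)], el[, c(4, 1, 5, 8)])
  keys <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  counts <- table(keys)
  expect_true(all(counts <= 2))
  expect_gt(sum(counts == 2), 0)
  # no orphan nodes
  expect_setequal(sort(unique(as.vector(el))), seq_len(nrow(m$nodes)))
})

test_that("body holes are absent from the element list and endcaps form two
          components", {
  field <- voxel_image(array(0.5, c(5, 5, 7)), 1)
  body <- voxel_image(array(0, c(5, 5, 7)), 1)
  body$data[, , 2:6] <- 1
  body$data[3, 3, 4] <- 0                        # hole
  capb <- voxel_image(array(0, c(5, 5, 7)), 1); capb$data[, , 1] <- 1
  capt <- voxel_image(array(0, c(5, 5, 7)), 1); capt$data[, , 7] <- 1
  body$data[, , 1] <- 0; body$data[, , 7] <- 0
  lay <- bone_layout(field, body)
  mesh <- build_mesh(lay, capb, capt)
  expect_equal(nrow(mesh$elements), sum(body$data) + 50)
  m <- aug_model()$mesh
  for (cap in c("endcap_bottom", "endcap_top"))
    expect_gt(sum(m$element_class == cap), 0)
  # the two endcap element sets never share a node
  nb <- unique(as.vector(m$elements[m$element_class == "endcap_bottom", ]))
  nt <- unique(as.vector(m$elements[m$element_class == "endcap_top", ]))
  expect_length(intersect(nb, nt), 0)
})

test_that("assign_materials implements the linear conversion with a floor", {
  mesh <- block_mesh(2, 2, 2)
  mesh$element_fraction <- c(1, 0, 0.5, 0.2, 1, 1, 0.7, 0.1)
  mat <- assign_materials(mesh, k = 0.0009)
  # full-intensity bone at the published factor: 255 * 0.0009 = 0.2295 GPa
  expect_equal(mat$E_gpa[1], 0.2295)
  expect_equal(mat$E_gpa[2], 1e-6)               # empty voxel floors
  expect_equal(mat$E_gpa[3], 255 * 0.0009 * 0.5)
  expect_true(all(mat$nu == 0.3))
  expect_true(all(is.na(mat$yield_pa)))
})

test_that("table-standard cards map onto cement, interface and endcaps", {
  m <- aug_model()$mesh
  mat <- assign_materials(m, k = 0.0009)
  cl <- as.character(m$element_class)
  expect_true(all(mat$E_gpa[cl == "cement"] == 1.7))
  expect_true(all(mat$nu[cl == "cement"] == 0.4))
  expect_true(all(mat$E_gpa[cl == "interface"] == 0.01))
  expect_true(all(mat$yield_pa[cl == "interface"] == 5))
  expect_true(all(mat$E_gpa[grepl("endcap", cl)] == 2.45))
  expect_true(all(mat$nu[grepl("endcap", cl)] == 0.3))
  expect_true(all(mat$E_gpa[cl == "needle"] == 1e-6))
  # missing card for a present class fails
  cards <- default_material_cards(); cards$cement <- NULL
  expect_error(assign_materials(m, 0.0009, cards), "missing material card")
})

test_that("assign_materials is homogeneous in k above the floor", {
  m <- aug_model()$mesh
  m1 <- assign_materials(m, 0.001)
  m2 <- assign_materials(m, 0.002)
  bone <- m$element_class == "bone" & m$element_fraction > 0
  expect_equal(m2$E_gpa[bone], 2 * m1$E_gpa[bone], tolerance = 1e-12)
  other <- !(m$element_class == "bone")
  expect_equal(m2$E_gpa[other], m1$E_gpa[other])
})

test_that("platen BCs fix the full inferior surface and reject off-footprint
          load points", {
  b <- aug_model()
  mesh <- b$mesh
  elb <- mesh$elements[mesh$element_class == "endcap_bottom", , drop = FALSE]
  zb <- min(mesh$nodes[as.vector(elb), 3])
  n_bottom <- length(unique(as.vector(elb)[
    abs(mesh$nodes[as.vector(elb), 3] - zb) < 1e-9]))
  expect_length(b$bcs$fixed_nodes, n_bottom)
  expect_error(build_bcs(mesh, c(100, 100, 20)), "outside")
})

test_that("a centred load on a symmetric model gives zero platen rotation,
          and moving it changes the reaction of an asymmetric model", {
  # symmetric block with endcaps
  d <- c(4, 4, 8)
  field <- voxel_image(array(0.5, d), 1)
  body <- voxel_image(array(0, d), 1); body$data[, , 3:6] <- 1
  capb <- voxel_image(array(0, d), 1); capb$data[, , 1:2] <- 1
  capt <- voxel_image(array(0, d), 1); capt$data[, , 7:8] <- 1
  mesh <- build_mesh(bone_layout(field, body), capb, capt)
  mat <- assign_materials(mesh, 0.0009)
  ctr <- c(mean(range(mesh$nodes[, 1])), mean(range(mesh$nodes[, 2])),
           max(mesh$nodes[, 3]))
  res <- solve_linear(model_definition(mesh, mat,
                                       build_bcs(mesh, ctr, 1)))
  expect_lt(max(abs(res$platen_rotation)), 1e-10)
  # asymmetric material: moving the load point changes the reaction
  mat2 <- mat
  left <- mesh$nodes[mesh$elements[, 1], 1] < ctr[1]
  mat2$E_gpa[mat2$E_gpa < 1 & left] <- 0.4
  r1 <- solve_linear(model_definition(mesh, mat2, build_bcs(mesh, ctr, 1)))
  r2 <- solve_linear(model_definition(mesh, mat2,
                                      build_bcs(mesh, ctr + c(0.8, 0, 0), 1)))
  expect_gt(abs(r1$platen_reaction - r2$platen_reaction),
            1e-6 * abs(r1$platen_reaction))
})

test_that("the INP export contains nodes, elements, sets and plastic cards", {
  b <- aug_model()
  model <- model_definition(b$mesh, assign_materials(b$mesh, 0.0009), b$bcs)
  path <- file.path(tempdir(), "model.inp")
  write_abaqus_inp(model, path)
  txt <- readLines(path)
  expect_true(any(grepl("^\\*ELEMENT, TYPE=C3D8", txt)))
  expect_true(any(grepl("ELSET=CEMENT", txt)))
  expect_true(any(grepl("^\\*PLASTIC", txt)))
  expect_true(any(grepl("ELSET=INTERFACE", txt)))
  n_nodes <- sum(grepl("^\\d+, ", txt[seq(which(txt == "*NODE") + 1,
                                          length.out = nrow(b$mesh$nodes))]))
  expect_equal(n_nodes, nrow(b$mesh$nodes))
})
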