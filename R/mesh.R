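#' Material card
#'
#' @param name region name.
#' @param youngs_modulus Young's modulus, GPa (> 0).
#' @param poisson_ratio Poisson ratio in \[0, 0.5).
#' @param yield_stress von Mises yield stress in Pa, or `NULL` for a purely
#'   elastic material. Yielded material is perfectly plastic (no hardening).
#' @return object of class `material_card`.
#' @export
material_card <- function(name, youngs_modulus, poisson_ratio,
                          yield_stress = NULL) {
  stopifnot(youngs_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5,
            is.null(yield_stress) || yield_stress > 0)
  structure(list(name = name, youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 yield_stress = yield_stress), class = "material_card")
}

#' Default material cards for the non-bone regions
#'
#' PMMA endcaps 2.45 GPa / 0.3; augmentation cement 1.7 GPa / 0.4;
#' cement-bone interface 0.01 GPa / 0.4 with a 5 Pa perfectly plastic von
#' Mises yield. The soft yielding interface represents, at continuum scale,
#' trabeculae at the cement border that are only partially constrained by
#' cement.
#'
#' @return named list of [material_card()]s (`endcap`, `cement`,
#'   `interface`).
#' @export
default_material_cards <- function() {
  list(endcap = material_card("PMMA endcap", 2.45, 0.3),
       cement = material_card("augmentation cement", 1.7, 0.4),
       interface = material_card("cement-bone interface", 0.01, 0.4,
                                 yield_stress = 5))
}

ELEMENT_CLASSES <- c("bone", "cement", "interface", "needle",
                     "endcap_bottom", "endcap_top")

#' Downsample a fine binary mask to coarse element occupancy
#'
#' Majority vote: a coarse voxel is set when at least half of its fine
#' source block is inside the mask.
#'
#' @param fine_mask binary `voxel_image`.
#' @param coarse_spacing target spacing, mm.
#' @return coarse binary `voxel_image`.
#' @export
coarse_mask <- function(fine_mask, coarse_spacing) {
  assert_binary(fine_mask)
  occ <- block_downsample(fine_mask,
                          coarse_factor(fine_mask$spacing, coarse_spacing))
  occ$data <- array(as.numeric(occ$data >= 0.5), dim(occ$data))
  occ
}

#' Non-augmented layout wrapper
#'
#' Wraps a bone field and body mask in the same layout structure an
#' augmented specimen uses, with empty cement/interface/needle classes, so
#' meshing is uniform across workflows.
#'
#' @param pre_field coarse fraction-field `voxel_image`.
#' @param body_mask coarse binary `voxel_image` on the same grid.
#' @return an `augmented_layout` with empty augmentation masks.
#' @export
bone_layout <- function(pre_field, body_mask) {
  build_augmented_layout(pre_field, body_mask, cement_mask_fine = NULL)
}

#' Build a voxel-hexahedral mesh
#'
#' One 8-node hexahedral element per retained coarse voxel (body plus the
#' two endcap slabs). Element classes follow the precedence endcaps >
#' cement > interface > needle > bone; bone elements carry their field
#' fraction `g` so materials can be mapped later. Sub-threshold bone voxels
#' are retained (they later receive the floor modulus), so mesh topology
#' does not depend on the conversion factor.
#'
#' @param layout an `augmented_layout` (see [bone_layout()] for the
#'   non-augmented case).
#' @param endcap_bottom,endcap_top coarse binary `voxel_image`s on the
#'   layout grid.
#' @return object of class `hex_mesh`: `nodes` (n x 3 mm), `elements`
#'   (m x 8 node indices, right-handed), `element_class`,
#'   `element_fraction`, `grid`, `edge_length`, and `couplings`
#'   (endcap-to-body node pairs tied in the axial dof only, representing
#'   frictionless no-separation endcap contact).
#' @export
build_mesh <- function(layout, endcap_bottom, endcap_top) {
  stopifnot(inherits(layout, "augmented_layout"))
  pf <- layout$bone_field
  d <- dim(pf$data)
  stopifnot(all(dim(endcap_bottom) == d), all(dim(endcap_top) == d))
  assert_binary(endcap_bottom); assert_binary(endcap_top)

  body <- layout$body_mask$data > 0
  capb <- endcap_bottom$data > 0 & !body
  capt <- endcap_top$data > 0 & !body
  if (!any(body)) stop("empty body mask: no bone elements to mesh")

  cls <- array(NA_character_, d)
  cls[body] <- "bone"
  cls[layout$needle_mask$data > 0 & body] <- "needle"
  cls[layout$interface_mask$data > 0 & body] <- "interface"
  cls[layout$cement_mask$data > 0 & body] <- "cement"
  cls[capb] <- "endcap_bottom"
  cls[capt] <- "endcap_top"

  vox <- which(!is.na(cls))
  nel <- length(vox)
  v0 <- vox - 1L
  i <- v0 %% d[1]
  j <- (v0 %/% d[1]) %% d[2]
  k <- v0 %/% (d[1] * d[2])

  ng <- d + 1L
  gid <- function(ii, jj, kk) 1L + ii + ng[1] * (jj + ng[2] * kk)
  conn <- cbind(gid(i,     j,     k),     gid(i + 1L, j,     k),
                gid(i + 1L, j + 1L, k),   gid(i,     j + 1L, k),
                gid(i,     j,     k + 1L), gid(i + 1L, j,     k + 1L),
                gid(i + 1L, j + 1L, k + 1L), gid(i,     j + 1L, k + 1L))

  used <- sort(unique(as.vector(conn)))
  remap <- integer(prod(ng))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[conn], nel, 8L)

  u0 <- used - 1L
  gi <- u0 %% ng[1]
  gj <- (u0 %/% ng[1]) %% ng[2]
  gk <- u0 %/% (ng[1] * ng[2])
  h <- pf$spacing
  corner0 <- pf$origin - h / 2
  nodes <- cbind(corner0[1] + gi * h, corner0[2] + gj * h,
                 corner0[3] + gk * h)

  element_class <- factor(cls[vox], levels = ELEMENT_CLASSES)
  element_fraction <- ifelse(element_class == "bone", pf$data[vox], 0)

  # frictionless (axial-only) endcap-bone ties: duplicate interface nodes so
  # the endcap elements keep their own lateral dofs
  body_nodes <- unique(as.vector(
    elements[!(element_class %in% c("endcap_bottom", "endcap_top")), ,
             drop = FALSE]))
  couplings <- NULL
  for (cap in c("endcap_bottom", "endcap_top")) {
    is_cap <- element_class == cap
    cap_nodes <- unique(as.vector(elements[is_cap, , drop = FALSE]))
    shared <- intersect(cap_nodes, body_nodes)
    if (length(shared) == 0L) next
    n_old <- nrow(nodes)
    dup_id <- seq_along(shared) + n_old
    nodes <- rbind(nodes, nodes[shared, , drop = FALSE])
    lut <- integer(n_old)
    lut[shared] <- dup_id
    capel <- elements[is_cap, , drop = FALSE]
    hit <- capel %in% shared
    capel[hit] <- lut[capel[hit]]
    elements[is_cap, ] <- capel
    couplings <- rbind(couplings,
                       data.frame(slave = dup_id, master = shared,
                                  side = sub("endcap_", "", cap)))
  }

  for (cap in c("endcap_bottom", "endcap_top"))
    if (!any(element_class == cap))
      stop(sprintf("no %s elements: endcap mask is empty", cap))
  if (is.null(couplings))
    stop("endcaps are disconnected from the body (no shared interface nodes)")

  structure(list(nodes = nodes, elements = elements,
                 element_class = element_class,
                 element_fraction = as.numeric(element_fraction),
                 grid = grid_spec(d, pf$spacing, pf$origin),
                 edge_length = h, voxel_index = vox,
                 couplings = couplings),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d hex8 elements (edge %g mm)\n",
              nrow(x$nodes), nrow(x$elements), x$edge_length))
  print(table(x$element_class))
  invisible(x)
}

#' Rectangular verification mesh
#'
#' A solid `nx x ny x nz` block of hex8 elements with no endcaps or
#' couplings, used for closed-form and patch-test verification of the
#' solver.
#'
#' @param nx,ny,nz element counts per axis.
#' @param edge element edge length, mm.
#' @param origin physical centre of voxel (0,0,0), mm.
#' @param class element class label for all elements.
#' @return a `hex_mesh`.
#' @export
block_mesh <- function(nx, ny, nz, edge = 1, origin = c(0, 0, 0),
                       class = "bone") {
  d <- c(nx, ny, nz)
  ng <- d + 1L
  nel <- prod(d)
  v0 <- seq_len(nel) - 1L
  i <- v0 %% d[1]; j <- (v0 %/% d[1]) %% d[2]; k <- v0 %/% (d[1] * d[2])
  gid <- function(ii, jj, kk) 1L + ii + ng[1] * (jj + ng[2] * kk)
  elements <- cbind(gid(i, j, k), gid(i + 1L, j, k), gid(i + 1L, j + 1L, k),
                    gid(i, j + 1L, k), gid(i, j, k + 1L),
                    gid(i + 1L, j, k + 1L), gid(i + 1L, j + 1L, k + 1L),
                    gid(i, j + 1L, k + 1L))
  u0 <- seq_len(prod(ng)) - 1L
  gi <- u0 %% ng[1]; gj <- (u0 %/% ng[1]) %% ng[2]; gk <- u0 %/% (ng[1] * ng[2])
  corner0 <- origin - edge / 2
  nodes <- cbind(corner0[1] + gi * edge, corner0[2] + gj * edge,
                 corner0[3] + gk * edge)
  structure(list(nodes = nodes, elements = elements,
                 element_class = factor(rep(class, nel),
                                        levels = ELEMENT_CLASSES),
                 element_fraction = rep(1, nel),
                 grid = grid_spec(d, edge, origin),
                 edge_length = edge, voxel_index = seq_len(nel),
                 couplings = NULL),
            class = "hex_mesh")
}

#' Uniform materials for a verification mesh
#'
#' @param mesh a `hex_mesh`.
#' @param E Young's modulus, GPa.
#' @param nu Poisson ratio.
#' @param yield_pa von Mises yield stress in Pa, `NA` for elastic.
#' @return a `model_materials` table.
#' @export
uniform_materials <- function(mesh, E, nu, yield_pa = NA_real_) {
  structure(data.frame(E_gpa = rep(E, nrow(mesh$elements)), nu = nu,
                       yield_pa = yield_pa),
            class = c("model_materials", "data.frame"))
}

#' Map element materials
#'
#' Bone elements get `E = max(255 * k * g, floor_modulus)` GPa, where `g`
#' is the element's fraction-field value in \[0, 1\] and `k` is the linear
#' grayscale-to-modulus conversion factor in GPa per 8-bit grayscale unit
#' (the factor 255 keeps published per-grayscale-unit values meaningful for
#' fields stored in \[0, 1\]). Cement, interface and endcap elements take
#' their cards; needle elements take the floor modulus (void).
#'
#' @param mesh a `hex_mesh`.
#' @param k conversion factor, GPa per grayscale unit (> 0).
#' @param cards named list of [material_card()]s with entries `endcap`,
#'   `cement`, `interface` (see [default_material_cards()]).
#' @param floor_modulus modulus assigned to empty/sub-threshold and needle
#'   elements, GPa; keeps the system nonsingular without deleting elements.
#' @param bone_poisson Poisson ratio for bone elements.
#' @return object of class `model_materials`: data.frame with per-element
#'   `E_gpa`, `nu`, `yield_pa` (NA = elastic).
#' @export
assign_materials <- function(mesh, k, cards = default_material_cards(),
                             floor_modulus = 1e-6, bone_poisson = 0.3) {
  stopifnot(inherits(mesh, "hex_mesh"), k > 0, floor_modulus > 0)
  cl <- as.character(mesh$element_class)
  need <- unique(cl)
  for (cc in intersect(need, c("cement", "interface"))) {
    if (is.null(cards[[cc]]))
      stop(sprintf("missing material card for present class '%s'", cc))
  }
  if (any(grepl("^endcap", need)) && is.null(cards$endcap))
    stop("missing material card for present class 'endcap'")
  n <- length(cl)
  E <- numeric(n); nu <- numeric(n); yield <- rep(NA_real_, n)
  bone <- cl == "bone"
  E[bone] <- pmax(255 * k * mesh$element_fraction[bone], floor_modulus)
  nu[bone] <- bone_poisson
  E[cl == "needle"] <- floor_modulus
  nu[cl == "needle"] <- bone_poisson
  for (cc in c("cement", "interface")) {
    sel <- cl == cc
    if (any(sel)) {
      E[sel] <- cards[[cc]]$youngs_modulus
      nu[sel] <- cards[[cc]]$poisson_ratio
      if (!is.null(cards[[cc]]$yield_stress))
        yield[sel] <- cards[[cc]]$yield_stress
    }
  }
  sel <- grepl("^endcap", cl)
  E[sel] <- cards$endcap$youngs_modulus
  nu[sel] <- cards$endcap$poisson_ratio
  structure(data.frame(E_gpa = E, nu = nu, yield_pa = yield),
            class = c("model_materials", "data.frame"))
}

point_in_hull_xy <- function(p, pts) {
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  nh <- length(hull)
  s <- 0
  for (ii in seq_len(nh)) {
    jj <- if (ii == nh) 1L else ii + 1L
    cr <- (hx[jj] - hx[ii]) * (p[2] - hy[ii]) -
          (hy[jj] - hy[ii]) * (p[1] - hx[ii])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

#' Boundary conditions: encastre base plus rigid loading platen
#'
#' The exterior (bottom) surface nodes of the inferior endcap are fully
#' fixed. The top surface nodes of the superior endcap are kinematically
#' coupled to a rigid platen located at `load_point`: the platen's lateral
#' translations are fixed, its axial translation is prescribed to
#' `-displacement`, and all three rotations are free, emulating load
#' applied through a ball joint.
#'
#' @param mesh a `hex_mesh`.
#' @param load_point physical mm position of the load application point;
#'   must lie over the superior endcap footprint.
#' @param displacement prescribed axial compression, mm (default 1).
#' @return object of class `bc_spec`.
#' @export
build_bcs <- function(mesh, load_point, displacement = 1.0) {
  stopifnot(inherits(mesh, "hex_mesh"), length(load_point) == 3L,
            displacement != 0)
  elb <- mesh$elements[mesh$element_class == "endcap_bottom", , drop = FALSE]
  elt <- mesh$elements[mesh$element_class == "endcap_top", , drop = FALSE]
  zb <- min(mesh$nodes[as.vector(elb), 3])
  zt <- max(mesh$nodes[as.vector(elt), 3])
  tol <- 1e-9 * max(1, abs(zt - zb))
  fixed_nodes <- sort(unique(as.vector(elb)[
    abs(mesh$nodes[as.vector(elb), 3] - zb) < tol]))
  platen_nodes <- sort(unique(as.vector(elt)[
    abs(mesh$nodes[as.vector(elt), 3] - zt) < tol]))
  if (!point_in_hull_xy(load_point[1:2],
                        mesh$nodes[platen_nodes, , drop = FALSE]))
    stop("load point lies outside the superior endcap footprint")
  structure(list(type = "platen", fixed_nodes = fixed_nodes,
                 platen_nodes = platen_nodes,
                 load_point = as.numeric(load_point),
                 displacement = displacement),
            class = "bc_spec")
}

#' Frictionless-column boundary conditions (verification variant)
#'
#' Prescribes the axial dof only: `u_z = -displacement` on the top node
#' plane, `u_z = 0` on the bottom node plane, lateral expansion free. Two
#' bottom nodes are pinned laterally (consistently with the uniform-strain
#' solution) to remove the remaining rigid-body modes, so a homogeneous
#' column reproduces the uniaxial closed form `S = E A / L` exactly.
#'
#' @inheritParams build_bcs
#' @return a `bc_spec` of type `"uniaxial"`.
#' @export
uniaxial_bcs <- function(mesh, displacement = 1.0) {
  z <- mesh$nodes[, 3]
  tol <- 1e-9 * max(1, diff(range(z)))
  bottom <- which(z < min(z) + tol)
  top <- which(z > max(z) - tol)
  ctr <- colMeans(mesh$nodes[bottom, 1:2, drop = FALSE])
  d2 <- (mesh$nodes[bottom, 1] - ctr[1])^2 + (mesh$nodes[bottom, 2] - ctr[2])^2
  pin_a <- bottom[which.min(d2)]
  same_y <- bottom[abs(mesh$nodes[bottom, 2] - mesh$nodes[pin_a, 2]) < tol &
                     bottom != pin_a]
  if (length(same_y) == 0L) stop("cannot pin lateral rigid modes")
  pin_b <- same_y[which.max(abs(mesh$nodes[same_y, 1] -
                                  mesh$nodes[pin_a, 1]))]
  structure(list(type = "uniaxial", bottom_nodes = bottom, top_nodes = top,
                 pin_a = pin_a, pin_b = pin_b,
                 displacement = displacement),
            class = "bc_spec")
}

#' Fully custom boundary conditions
#'
#' Low-level escape hatch used for verification (e.g. the linear patch
#' test): prescribe arbitrary dof values directly.
#'
#' @param prescribed_dofs integer dof indices (node `n` owns dofs
#'   `3n-2, 3n-1, 3n` for x, y, z).
#' @param values prescribed displacements (mm), same length.
#' @param reaction_dofs dofs whose reactions are summed into
#'   `platen_reaction` (defaults to the prescribed set).
#' @export
custom_bcs <- function(prescribed_dofs, values,
                       reaction_dofs = prescribed_dofs) {
  stopifnot(length(prescribed_dofs) == length(values))
  structure(list(type = "custom",
                 prescribed_dofs = as.integer(prescribed_dofs),
                 values = as.numeric(values),
                 reaction_dofs = as.integer(reaction_dofs),
                 displacement = NA_real_),
            class = "bc_spec")
}

#' Solvable model: mesh + materials + boundary conditions
#'
#' @param mesh a `hex_mesh`.
#' @param materials a `model_materials` table (see [assign_materials()]).
#' @param bcs a `bc_spec`.
#' @return object of class `model_definition`.
#' @export
model_definition <- function(mesh, materials, bcs) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(materials, "model_materials"),
            inherits(bcs, "bc_spec"),
            nrow(materials) == nrow(mesh$elements))
  structure(list(mesh = mesh, materials = materials, bcs = bcs),
            class = "model_definition")
}

#' @export
print.model_definition <- function(x, ...) {
  cat(sprintf("<model_definition> %d elements, %d nodes, BC type '%s'\n",
              nrow(x$mesh$elements), nrow(x$mesh$nodes), x$bcs$type))
  invisible(x)
}

#' Export a model as an Abaqus input deck
#'
#' Writes nodes, C3D8 elements, per-class element sets and per-element
#' solid sections with elastic (and perfectly plastic, where a yield is
#' set) materials, for cross-checking against commercial solvers. Boundary
#' conditions are written for the encastre base; the platen coupling is
#' left to the receiving pre-processor.
#'
#' @param model a `model_definition`.
#' @param path output `.inp` path.
#' @export
write_abaqus_inp <- function(model, path) {
  mesh <- model$mesh; mat <- model$materials
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("*HEADING")
  w("voxel hexahedral vertebra model (units: mm, N, MPa)")
  w("*NODE")
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("*ELEMENT, TYPE=C3D8")
  writeLines(sprintf("%d, %s", seq_len(nrow(mesh$elements)),
                     apply(mesh$elements, 1, paste, collapse = ", ")), con)
  for (cc in levels(mesh$element_class)) {
    ids <- which(mesh$element_class == cc)
    if (length(ids) == 0L) next
    w("*ELSET, ELSET=%s", toupper(cc))
    writeLines(paste(ids, collapse = ", "), con)
  }
  key <- sprintf("%.12g|%.6g|%s", mat$E_gpa, mat$nu,
                 ifelse(is.na(mat$yield_pa), "el", format(mat$yield_pa)))
  groups <- split(seq_len(nrow(mat)), key)
  mi <- 0L
  for (g in groups) {
    mi <- mi + 1L
    nm <- sprintf("MAT%d", mi)
    w("*ELSET, ELSET=SET_%s", nm)
    writeLines(paste(g, collapse = ", "), con)
    w("*SOLID SECTION, ELSET=SET_%s, MATERIAL=%s", nm, nm)
    w("*MATERIAL, NAME=%s", nm)
    w("*ELASTIC")
    w("%.9g, %.6g", mat$E_gpa[g[1]] * 1000, mat$nu[g[1]])  # MPa
    if (!is.na(mat$yield_pa[g[1]])) {
      w("*PLASTIC")
      w("%.9g, 0.", mat$yield_pa[g[1]] * 1e-6)              # MPa
    }
  }
  if (model$bcs$type == "platen") {
    w("*NSET, NSET=FIXED")
    writeLines(paste(model$bcs$fixed_nodes, collapse = ", "), con)
    w("*NSET, NSET=PLATEN")
    writeLines(paste(model$bcs$platen_nodes, collapse = ", "), con)
    w("*BOUNDARY")
    w("FIXED, 1, 3, 0.")
  }
  invisible(path)
}
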