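#' Solver configuration
#'
#' @param linear_tol relative residual tolerance used to verify the linear
#'   solve (the factorisation itself is direct).
#' @param max_newton maximum equilibrium iterations per load increment.
#' @param newton_tol relative force-residual tolerance for equilibrium
#'   iterations.
#' @param n_increments number of displacement increments for the
#'   elastoplastic solve.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(linear_tol = 1e-8, max_newton = 30L,
                          newton_tol = 1e-6, n_increments = 10L) {
  stopifnot(linear_tol > 0, linear_tol < 1, newton_tol > 0, newton_tol < 1,
            max_newton >= 1L, n_increments >= 1L)
  structure(list(linear_tol = linear_tol, max_newton = as.integer(max_newton),
                 newton_tol = newton_tol,
                 n_increments = as.integer(n_increments)),
            class = "solver_config")
}

# Build the kinematic constraint map u = T q + c * scale for a bc_spec.
# Returns T (ndof x nq sparse), c (unit-displacement constant vector),
# reaction dof set, and the q indices of the platen rotations (if any).
build_constraints <- function(mesh, bcs) {
  ndof <- 3L * nrow(mesh$nodes)
  dof_state <- integer(ndof)           # 0 free, 1 fixed/prescribed, 2 coupled
  cvec <- numeric(ndof)
  ti <- list(); tj <- list(); tx <- list()

  slave_z <- integer(0); master_z <- integer(0)
  if (!is.null(mesh$couplings)) {
    slave_z <- 3L * mesh$couplings$slave
    master_z <- 3L * mesh$couplings$master
    dof_state[slave_z] <- 2L
  }

  platen_rot_q <- integer(0)
  reaction_dofs <- integer(0)
  extra_q <- 0L

  if (bcs$type == "platen") {
    fx <- as.vector(outer(c(-2L, -1L, 0L), 3L * bcs$fixed_nodes, "+"))
    dof_state[fx] <- 1L
    pz <- 3L * bcs$platen_nodes
    px <- pz - 2L; py <- pz - 1L
    dof_state[c(px, py, pz)] <- 1L
    cvec[pz] <- -1                      # unit prescribed axial displacement
    reaction_dofs <- pz
    extra_q <- 2L                       # platen tilt rotations theta_x/y
    # The axial-only endcap couplings transmit no shear, so the body (and
    # the platen about its own axis) would otherwise float laterally/spin
    # at zero energy. Pin two body nodes at the inferior interface, chosen
    # consistently with a uniform-deformation field, and keep the platen
    # spin theta_z fixed.
    if (!is.null(mesh$couplings)) {
      mb <- mesh$couplings$master[mesh$couplings$side == "bottom"]
      if (length(mb) >= 2L) {
        ctr <- colMeans(mesh$nodes[mb, 1:2, drop = FALSE])
        d2 <- (mesh$nodes[mb, 1] - ctr[1])^2 + (mesh$nodes[mb, 2] - ctr[2])^2
        pin_a <- mb[which.min(d2)]
        same_y <- mb[abs(mesh$nodes[mb, 2] - mesh$nodes[pin_a, 2]) <
                       1e-9 & mb != pin_a]
        dof_state[c(3L * pin_a - 2L, 3L * pin_a - 1L)] <- 1L
        if (length(same_y) > 0L) {
          pin_b <- same_y[which.max(abs(mesh$nodes[same_y, 1] -
                                          mesh$nodes[pin_a, 1]))]
          dof_state[3L * pin_b - 1L] <- 1L
        }
      }
    }
  } else if (bcs$type == "uniaxial") {
    bz <- 3L * bcs$bottom_nodes
    tz <- 3L * bcs$top_nodes
    dof_state[c(bz, tz)] <- 1L
    cvec[tz] <- -1
    # pin_a blocks both lateral translations; pin_b (same y, different x)
    # blocks rotation about z via its y component, consistently with the
    # uniform-strain solution
    pins <- c(3L * bcs$pin_a - 2L, 3L * bcs$pin_a - 1L, 3L * bcs$pin_b - 1L)
    dof_state[pins] <- 1L
    reaction_dofs <- tz
  } else if (bcs$type == "custom") {
    dof_state[bcs$prescribed_dofs] <- 1L
    cvec[bcs$prescribed_dofs] <- bcs$values
    reaction_dofs <- bcs$reaction_dofs
  } else stop("unknown bc type")

  free <- which(dof_state == 0L)
  nq <- length(free) + extra_q
  qidx <- integer(ndof)
  qidx[free] <- seq_along(free)
  ti[[1]] <- free; tj[[1]] <- qidx[free]; tx[[1]] <- rep(1, length(free))

  if (length(slave_z) > 0L) {
    # slave axial dof follows its master; master must itself be free
    if (any(dof_state[master_z] != 0L))
      stop("coupling master dof is constrained; unsupported configuration")
    ti[[length(ti) + 1L]] <- slave_z
    tj[[length(tj) + 1L]] <- qidx[master_z]
    tx[[length(tx) + 1L]] <- rep(1, length(slave_z))
  }

  if (bcs$type == "platen") {
    qr <- length(free) + 1:2
    platen_rot_q <- qr
    dxyz <- sweep(mesh$nodes[bcs$platen_nodes, , drop = FALSE], 2,
                  bcs$load_point)
    px <- 3L * bcs$platen_nodes - 2L
    py <- 3L * bcs$platen_nodes - 1L
    pz <- 3L * bcs$platen_nodes
    # u = theta x (x - x0) with theta_z = 0 (the ball joint frees the tilt
    # rotations; spin about the load axis carries no load path through the
    # frictionless endcap interfaces and is held at zero):
    # ux = ty*dz; uy = -tx*dz; uz = tx*dy - ty*dx
    ti[[length(ti) + 1L]] <- c(px, py, pz, pz)
    tj[[length(tj) + 1L]] <- c(rep(qr[2], length(px)),
                               rep(qr[1], length(py)),
                               rep(qr[1], length(pz)), rep(qr[2], length(pz)))
    tx[[length(tx) + 1L]] <- c(dxyz[, 3], -dxyz[, 3],
                               dxyz[, 2], -dxyz[, 1])
  }

  T <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(ndof, nq))
  list(T = T, c = cvec, reaction_dofs = reaction_dofs,
       platen_rot_q = platen_rot_q, nq = nq)
}

# per-element Lame parameters in MPa from a model_materials table
materials_lame <- function(materials) {
  E_mpa <- materials$E_gpa * 1000
  list(lam = lame_lambda(E_mpa, materials$nu),
       mu = lame_mu(E_mpa, materials$nu))
}

solve_reduced <- function(K, con, scale, chol_cache = NULL) {
  Kred <- Matrix::forceSymmetric(Matrix::crossprod(con$T, K %*% con$T))
  ch <- tryCatch(
    if (is.null(chol_cache)) Matrix::Cholesky(Kred, LDL = FALSE, super = TRUE, perm = TRUE)
    else Matrix::update(chol_cache, Kred),
    error = function(e) stop(
      "singular constrained system (unconstrained rigid-body components?): ",
      conditionMessage(e)))
  cfull <- con$c * scale
  rhs <- -as.vector(Matrix::crossprod(con$T, K %*% cfull))
  q <- as.vector(Matrix::solve(ch, rhs))
  u <- as.vector(con$T %*% q) + cfull
  list(q = q, u = u, chol = ch)
}

von_mises_of <- function(sig) {
  # sig: n x 6 Voigt stress (xx yy zz xy yz zx)
  p <- (sig[, 1] + sig[, 2] + sig[, 3]) / 3
  sqrt(pmax(0, 1.5 * ((sig[, 1] - p)^2 + (sig[, 2] - p)^2 +
                        (sig[, 3] - p)^2) +
              3 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2)))
}

# elastic stress recovery: max von Mises over Gauss points per element (MPa)
elastic_von_mises <- function(mesh, materials, u) {
  base <- hex8_base(mesh$edge_length)
  lm <- materials_lame(materials)
  edof <- element_dofs(mesh$elements)
  ue <- matrix(u[edof], nrow(edof), 24L)
  vm <- numeric(nrow(edof))
  for (q in 1:8) {
    eps <- ue %*% t(base$B[[q]])
    sig <- voigt_stress(eps, lm$lam, lm$mu)
    vm <- pmax(vm, von_mises_of(sig))
  }
  vm
}

# isotropic stress from strain rows (engineering shear), vectorised
voigt_stress <- function(eps, lam, mu) {
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  cbind(lam * tr + 2 * mu * eps[, 1],
        lam * tr + 2 * mu * eps[, 2],
        lam * tr + 2 * mu * eps[, 3],
        mu * eps[, 4], mu * eps[, 5], mu * eps[, 6])
}

finish_result <- function(mesh, con, u, K, bcs, vm_mpa, iterations,
                          converged, dissipation = numeric(0)) {
  r <- as.vector(K %*% u)
  reaction <- -sum(r[con$reaction_dofs])   # + = compressive platen force, N
  structure(list(
    nodal_displacements = matrix(u, ncol = 3L, byrow = TRUE),
    u = as.numeric(u),
    platen_reaction = reaction,
    platen_rotation = attr(u, "platen_rotation"),
    element_von_mises = vm_mpa * 1e6,    # Pa
    residual = r,
    prescribed_displacement = if (!is.na(bcs$displacement)) bcs$displacement
      else NA_real_,
    iterations = iterations, converged = converged,
    plastic_dissipation = dissipation),
    class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result> reaction %.4g N, %d iteration(s), converged: %s\n",
              x$platen_reaction, x$iterations, x$converged))
  invisible(x)
}

#' Linear elastic solve
#'
#' Assembles the sparse global stiffness (all materials treated as
#' elastic), eliminates the boundary and platen constraints through a
#' kinematic transformation matrix, and solves the reduced symmetric
#' positive-definite system with a sparse Cholesky factorisation. The
#' platen reaction is the axial constraint force conjugate to the
#' prescribed displacement.
#'
#' @param model a `model_definition`.
#' @param config a [solver_config()].
#' @return a `solve_result` with nodal displacements (mm), `platen_reaction`
#'   (N, positive in compression), `platen_rotation` (rad, platen BCs only)
#'   and per-element von Mises stress (Pa).
#' @export
solve_linear <- function(model, config = solver_config()) {
  mesh <- model$mesh
  lm <- materials_lame(model$materials)
  K <- assemble_stiffness(mesh, lm$lam, lm$mu)
  con <- build_constraints(mesh, model$bcs)
  scale <- if (!is.na(model$bcs$displacement)) model$bcs$displacement else 1
  sol <- solve_reduced(K, con, scale)
  u <- sol$u
  if (length(con$platen_rot_q) > 0)
    attr(u, "platen_rotation") <- sol$q[con$platen_rot_q]
  # verification of the direct solve against the stated tolerance
  rred <- as.vector(Matrix::crossprod(con$T, K %*% u))
  ref <- max(abs(as.vector(K %*% u)), 1e-300)
  converged <- (if (length(rred)) max(abs(rred)) else 0) <=
    config$linear_tol * ref
  vm <- elastic_von_mises(mesh, model$materials, u)
  finish_result(mesh, con, u, K, model$bcs, vm, 1L, converged)
}

# J2 perfectly plastic radial return, vectorised over rows.
# eps_e_tr: trial elastic strain (eng shear); returns stress, updated
# plastic strain increment, and plastic multiplier dgamma.
radial_return <- function(eps_e_tr, lam, mu, sigy) {
  sig_tr <- voigt_stress(eps_e_tr, lam, mu)
  q_tr <- von_mises_of(sig_tr)
  yielded <- q_tr > sigy
  sig <- sig_tr
  n <- nrow(sig_tr)
  dgamma <- numeric(n)
  depsp <- matrix(0, n, 6L)
  m_dir <- matrix(0, n, 6L)            # unit deviatoric direction (tensor)
  theta <- rep(1, n)                   # sigy/q_trial for yielded points
  if (any(yielded)) {
    y <- which(yielded)
    p <- (sig_tr[y, 1] + sig_tr[y, 2] + sig_tr[y, 3]) / 3
    s <- sig_tr[y, , drop = FALSE]
    s[, 1] <- s[, 1] - p; s[, 2] <- s[, 2] - p; s[, 3] <- s[, 3] - p
    fac <- sigy[y] / q_tr[y]
    sig[y, ] <- s * fac
    sig[y, 1] <- sig[y, 1] + p
    sig[y, 2] <- sig[y, 2] + p
    sig[y, 3] <- sig[y, 3] + p
    dg <- (q_tr[y] - sigy[y]) / (3 * mu[y])
    dgamma[y] <- dg
    nfac <- 1.5 * dg / q_tr[y]
    depsp[y, 1:3] <- s[, 1:3] * nfac
    depsp[y, 4:6] <- s[, 4:6] * (2 * nfac)   # engineering shear
    snorm <- sqrt(rowSums(s[, 1:3, drop = FALSE]^2) +
                    2 * rowSums(s[, 4:6, drop = FALSE]^2))
    m_dir[y, ] <- s / snorm
    theta[y] <- fac
  }
  list(sig = sig, depsp = depsp, dgamma = dgamma, yielded = yielded,
       m = m_dir, theta = theta)
}

# Voigt deviatoric projector acting on engineering-shear strain
IDEV_VOIGT <- local({
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- diag(3) - 1 / 3
  M[4:6, 4:6] <- diag(3) * 0.5
  M
})
ONE_OUTER <- local({M <- matrix(0, 6, 6); M[1:3, 1:3] <- 1; M})

#' Elastoplastic solve (yielding interface elements)
#'
#' Monotonic displacement-controlled ramp in `n_increments` steps. Elements
#' whose material carries a yield stress follow J2 (von Mises) perfect
#' plasticity with radial-return mapping at each of their 8 Gauss points;
#' all other elements stay linear elastic. Equilibrium within each
#' increment uses Newton iterations with the algorithmically consistent
#' elastoplastic tangent on the force residual.
#'
#' @inheritParams solve_linear
#' @return a `solve_result`; `plastic_dissipation` holds the (non-negative)
#'   dissipated energy per increment (N mm).
#' @export
solve_elastoplastic <- function(model, config = solver_config()) {
  mesh <- model$mesh
  mat <- model$materials
  plastic <- which(!is.na(mat$yield_pa))
  if (length(plastic) == 0L) return(solve_linear(model, config))
  lm <- materials_lame(mat)
  base <- hex8_base(mesh$edge_length)
  ndof <- 3L * nrow(mesh$nodes)

  K_other <- assemble_stiffness(mesh, lm$lam, lm$mu,
                                subset = setdiff(seq_len(nrow(mat)), plastic))
  con <- build_constraints(mesh, model$bcs)
  K_other_red <- Matrix::forceSymmetric(
    Matrix::crossprod(con$T, K_other %*% con$T))

  edofP <- element_dofs(mesh$elements)[plastic, , drop = FALSE]
  lamP <- lm$lam[plastic]; muP <- lm$mu[plastic]
  sigyP <- mat$yield_pa[plastic] * 1e-6            # Pa -> MPa
  nP <- length(plastic)
  epsp <- lapply(1:8, function(q) matrix(0, nP, 6L))

  # internal force and gauss stresses of the plastic set at displacement u
  plastic_state <- function(u) {
    ue <- matrix(u[edofP], nP, 24L)
    fe <- matrix(0, nP, 24L)
    sig_q <- vector("list", 8L)
    depsp_q <- vector("list", 8L)
    dgam_q <- vector("list", 8L)
    rr_q <- vector("list", 8L)
    for (q in 1:8) {
      eps <- ue %*% t(base$B[[q]])
      rr <- radial_return(eps - epsp[[q]], lamP, muP, sigyP)
      sig_q[[q]] <- rr$sig
      depsp_q[[q]] <- rr$depsp
      dgam_q[[q]] <- rr$dgamma
      rr_q[[q]] <- rr
      fe <- fe + (rr$sig %*% base$B[[q]]) * base$wdet
    }
    fvec <- numeric(ndof)
    agg <- rowsum(as.vector(fe), as.vector(edofP))
    fvec[as.integer(rownames(agg))] <- agg
    list(f = fvec, sig = sig_q, depsp = depsp_q, dgamma = dgam_q,
         rr = rr_q)
  }

  KbP <- lamP + 2 * muP / 3            # bulk modulus of the plastic set
  KlamV <- as.vector(base$Klam); KmuV <- as.vector(base$Kmu)
  # consistent tangent stiffness of the plastic elements (sparse, full dofs)
  plastic_tangent <- function(ps) {
    anyY <- Reduce(`|`, lapply(ps$rr, function(r) r$yielded))
    Xe <- matrix(0, nP, 576L)
    el_idx <- which(anyY)
    if (length(el_idx) < nP) {
      ee <- which(!anyY)               # fully elastic: closed-form split
      Xe[ee, ] <- lamP[ee] %o% KlamV + muP[ee] %o% KmuV
    }
    for (e in el_idx) {
      Ke <- matrix(0, 24, 24)
      for (qq in 1:8) {
        r <- ps$rr[[qq]]
        D <- if (r$yielded[e]) {
          th <- r$theta[e]; mv <- r$m[e, ]
          KbP[e] * ONE_OUTER + 2 * muP[e] * th * (IDEV_VOIGT - mv %o% mv)
        } else {
          lamP[e] * ONE_OUTER + muP[e] * diag(c(2, 2, 2, 1, 1, 1))
        }
        B <- base$B[[qq]]
        Ke <- Ke + base$wdet * crossprod(B, D %*% B)
      }
      Xe[e, ] <- as.vector(Ke)
    }
    pa <- rep(1:24, times = 24); pb <- rep(1:24, each = 24)
    Matrix::sparseMatrix(i = as.vector(edofP[, pa]),
                         j = as.vector(edofP[, pb]),
                         x = as.vector(Xe), dims = c(ndof, ndof))
  }

  scale <- if (!is.na(model$bcs$displacement)) model$bcs$displacement else 1
  n_inc <- config$n_increments
  q <- numeric(con$nq)
  dissipation <- numeric(n_inc)
  total_iters <- 0L
  ps <- NULL
  for (inc in seq_len(n_inc)) {
    cfull <- con$c * (scale * inc / n_inc)
    converged <- FALSE
    for (it in seq_len(config$max_newton)) {
      u <- as.vector(con$T %*% q) + cfull
      ps <- plastic_state(u)
      fint <- as.vector(K_other %*% u) + ps$f
      rred <- as.vector(Matrix::crossprod(con$T, fint))
      ref <- max(sum(abs(fint[con$reaction_dofs])), 1e-10)
      total_iters <- total_iters + 1L
      rmax <- if (length(rred)) max(abs(rred)) else 0
      if (rmax <= config$newton_tol * ref) { converged <- TRUE; break }
      K_pl <- plastic_tangent(ps)
      Kred <- K_other_red +
        Matrix::forceSymmetric(Matrix::crossprod(con$T, K_pl %*% con$T))
      ch <- tryCatch(
        Matrix::Cholesky(Matrix::forceSymmetric(Kred), LDL = FALSE,
                         super = TRUE, perm = TRUE),
        error = function(e) stop(
          "singular elastoplastic tangent: ", conditionMessage(e)))
      q <- q + as.vector(Matrix::solve(ch, -rred))
    }
    if (!converged)
      stop(sprintf(
        "Newton did not converge in %d iterations at increment %d/%d (residual %.3g)",
        config$max_newton, inc, n_inc, rmax))
    # commit plastic state and accumulate dissipation (sigy * dgamma >= 0)
    for (qq in 1:8) {
      epsp[[qq]] <- epsp[[qq]] + ps$depsp[[qq]]
      dissipation[inc] <- dissipation[inc] +
        sum(sigyP * ps$dgamma[[qq]]) * base$wdet
    }
  }

  u <- as.vector(con$T %*% q) + con$c * scale
  if (length(con$platen_rot_q) > 0)
    attr(u, "platen_rotation") <- q[con$platen_rot_q]
  vm <- elastic_von_mises(mesh, mat, u)
  # overwrite the plastic elements' von Mises with the mapped stresses
  vmP <- numeric(nP)
  for (qq in 1:8) vmP <- pmax(vmP, von_mises_of(ps$sig[[qq]]))
  vm[plastic] <- vmP
  fint <- as.vector(K_other %*% u) + ps$f
  r <- fint
  reaction <- -sum(r[con$reaction_dofs])
  structure(list(
    nodal_displacements = matrix(u, ncol = 3L, byrow = TRUE),
    u = as.numeric(u),
    platen_reaction = reaction,
    platen_rotation = attr(u, "platen_rotation"),
    element_von_mises = vm * 1e6,
    residual = r,
    prescribed_displacement = scale,
    iterations = total_iters, converged = TRUE,
    plastic_dissipation = dissipation),
    class = "solve_result")
}

#' Model stiffness from a solved result
#'
#' @param result a `solve_result`.
#' @param prescribed_displacement prescribed axial displacement, mm
#'   (defaults to the value stored in the result).
#' @return stiffness in N/mm.
#' @export
model_stiffness <- function(result,
                            prescribed_displacement =
                              result$prescribed_displacement) {
  stopifnot(inherits(result, "solve_result"))
  if (is.na(prescribed_displacement) || prescribed_displacement == 0)
    stop("prescribed displacement must be nonzero")
  if (!isTRUE(result$converged)) stop("result did not converge")
  result$platen_reaction / prescribed_displacement
}

#' Precompute a fast stiffness-vs-conversion-factor evaluator
#'
#' For conversion-factor calibration the same model is re-solved at many
#' candidate `k`. Away from the floor-modulus regime the global stiffness
#' matrix is exactly affine in `k` (`K = k A + B`), so the assembly and the
#' symbolic Cholesky analysis can be done once and each candidate costs a
#' numeric refactorisation only. Exactness is preserved: whenever a
#' candidate `k` would push any nonzero-fraction bone element below the
#' floor modulus the evaluator falls back to full reassembly via
#' [assign_materials()] and [solve_linear()].
#'
#' @param mesh a `hex_mesh`.
#' @param bcs a `bc_spec`.
#' @param cards,floor_modulus,bone_poisson as in [assign_materials()].
#' @param config a [solver_config()].
#' @return `function(k)` returning the model stiffness in N/mm.
#' @export
make_stiffness_fn <- function(mesh, bcs, cards = default_material_cards(),
                              floor_modulus = 1e-6, bone_poisson = 0.3,
                              config = solver_config()) {
  cl <- as.character(mesh$element_class)
  g <- mesh$element_fraction
  bone_var <- which(cl == "bone" & g > 0)
  # unit-k materials: bone E-coefficient 255*g GPa, everything else constant
  mat1 <- assign_materials(mesh, k = 1, cards = cards,
                           floor_modulus = floor_modulus,
                           bone_poisson = bone_poisson)
  lm1 <- materials_lame(mat1)
  # lambda and mu both scale linearly with E, so the unit-k bone assembly A
  # scales exactly with k
  A <- assemble_stiffness(mesh, lm1$lam, lm1$mu, subset = bone_var)
  B <- assemble_stiffness(mesh, lm1$lam, lm1$mu,
                          subset = setdiff(seq_len(nrow(mat1)), bone_var))
  con <- build_constraints(mesh, bcs)
  Ared <- Matrix::forceSymmetric(Matrix::crossprod(con$T, A %*% con$T))
  Bred <- Matrix::forceSymmetric(Matrix::crossprod(con$T, B %*% con$T))
  scale <- if (!is.na(bcs$displacement)) bcs$displacement else 1
  cfull <- con$c * scale
  fA <- -as.vector(Matrix::crossprod(con$T, A %*% cfull))
  fB <- -as.vector(Matrix::crossprod(con$T, B %*% cfull))
  gmin <- if (length(bone_var) > 0) min(g[bone_var]) else Inf
  cache <- new.env(parent = emptyenv())

  function(k) {
    stopifnot(k > 0)
    key <- sprintf("%.17g", k)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- if (255 * k * gmin < floor_modulus) {
      mat <- assign_materials(mesh, k, cards, floor_modulus, bone_poisson)
      res <- solve_linear(model_definition(mesh, mat, bcs), config)
      model_stiffness(res, scale)
    } else {
      Kred <- Matrix::forceSymmetric(k * Ared + Bred)
      ch <- Matrix::Cholesky(Kred, LDL = FALSE, super = TRUE, perm = TRUE)
      q <- as.vector(Matrix::solve(ch, k * fA + fB))
      u <- as.vector(con$T %*% q) + cfull
      r <- as.vector(k * (A %*% u) + B %*% u)
      -sum(r[con$reaction_dofs]) / scale
    }
    cache[[key]] <- s
    s
  }
}

#' Export a solved model as a legacy VTK unstructured grid
#'
#' ASCII VTK with nodal displacements (mm) and per-element von Mises
#' stress (Pa), for visualisation in ParaView and similar tools.
#'
#' @param mesh a `hex_mesh`.
#' @param result a `solve_result` for that mesh.
#' @param path output `.vtk` path.
#' @export
write_vtk <- function(mesh, result, path) {
  con <- file(path, "w"); on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "voxel hexahedral vertebra model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  e0 <- mesh$elements - 1L
  writeLines(paste(8L, e0[, 1], e0[, 2], e0[, 3], e0[, 4], e0[, 5], e0[, 6],
                   e0[, 7], e0[, 8]), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)                     # VTK_HEXAHEDRON
  writeLines(c(sprintf("POINT_DATA %d", nn),
               "VECTORS displacement double"), con)
  ud <- result$nodal_displacements
  writeLines(sprintf("%.9g %.9g %.9g", ud[, 1], ud[, 2], ud[, 3]), con)
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS von_mises_pa double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", result$element_von_mises), con)
  invisible(path)
}

#' JSON summary of a solve
#'
#' @param result a `solve_result`.
#' @param path output `.json` path.
#' @export
write_solve_summary <- function(result, path) {
  jsonlite::write_json(
    list(platen_reaction_N = result$platen_reaction,
         prescribed_displacement_mm = result$prescribed_displacement,
         stiffness_N_per_mm = if (!is.na(result$prescribed_displacement))
           result$platen_reaction / result$prescribed_displacement,
         iterations = result$iterations,
         converged = result$converged,
         plastic_dissipation_Nmm = result$plastic_dissipation),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
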