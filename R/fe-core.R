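# Trilinear 8-node hexahedron on a cubic voxel: shape-function gradients,
# strain-displacement matrices at the 2x2x2 Gauss points, and the element
# stiffness split K = lambda * K_lam + mu * K_mu that makes assembly of
# per-element isotropic materials a pure scaling operation.

# natural coordinates of the local nodes, matching mesh connectivity order
HEX8_XI <- matrix(c(-1, -1, -1,   1, -1, -1,   1, 1, -1,  -1, 1, -1,
                    -1, -1,  1,   1, -1,  1,   1, 1,  1,  -1, 1,  1),
                  nrow = 8, byrow = TRUE)

# B matrix (6 x 24, Voigt xx yy zz xy yz zx with engineering shear) at one
# natural point for edge length h
hex8_B <- function(xi, h) {
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    s <- HEX8_XI[a, ]
    dN[a, 1] <- s[1] / 8 * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3])
    dN[a, 2] <- s[2] / 8 * (1 + s[1] * xi[1]) * (1 + s[3] * xi[3])
    dN[a, 3] <- s[3] / 8 * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2])
  }
  dN <- dN * 2 / h                     # J = (h/2) I for a cubic element
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[a, 1]
    B[2, c0 + 2] <- dN[a, 2]
    B[3, c0 + 3] <- dN[a, 3]
    B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
    B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
    B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
  }
  B
}

# Gauss-point data and the lambda/mu stiffness split for edge length h;
# memoised because every element of a voxel mesh shares the same geometry
hex8_base_env <- new.env(parent = emptyenv())

hex8_base <- function(h) {
  key <- format(h, digits = 17)
  if (!is.null(hex8_base_env[[key]])) return(hex8_base_env[[key]])
  gp <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-gp, gp), eta = c(-gp, gp),
                               zeta = c(-gp, gp)))
  wdet <- (h / 2)^3                    # unit Gauss weights
  P_lam <- matrix(0, 6, 6); P_lam[1:3, 1:3] <- 1
  P_mu <- diag(c(2, 2, 2, 1, 1, 1))
  Bs <- vector("list", 8L)
  Klam <- matrix(0, 24, 24); Kmu <- matrix(0, 24, 24)
  for (q in 1:8) {
    B <- hex8_B(pts[q, ], h)
    Bs[[q]] <- B
    Klam <- Klam + wdet * t(B) %*% P_lam %*% B
    Kmu <- Kmu + wdet * t(B) %*% P_mu %*% B
  }
  out <- list(B = Bs, wdet = wdet, Klam = Klam, Kmu = Kmu)
  hex8_base_env[[key]] <- out
  out
}

lame_lambda <- function(E, nu) E * nu / ((1 + nu) * (1 - 2 * nu))
lame_mu <- function(E, nu) E / (2 * (1 + nu))

#' Element stiffness matrix of a cubic hex8 element
#'
#' Trilinear hexahedron with 2 x 2 x 2 Gauss integration on a cube of the
#' given edge length. The matrix is symmetric, linear in `E`, and has
#' exactly six (rigid-body) zero eigenvalues. Units follow the inputs: with
#' `E` in MPa and `edge_length` in mm the entries are N/mm.
#'
#' @param E Young's modulus.
#' @param nu Poisson ratio in \[0, 0.5).
#' @param edge_length cube edge length.
#' @return 24 x 24 numeric matrix (3 dofs per node, local node order
#'   matching the mesh connectivity).
#' @export
hex8_stiffness <- function(E, nu, edge_length = 1) {
  stopifnot(E > 0, nu >= 0, edge_length > 0)
  if (nu >= 0.5) stop("Poisson ratio must be < 0.5")
  base <- hex8_base(edge_length)
  lame_lambda(E, nu) * base$Klam + lame_mu(E, nu) * base$Kmu
}

# element dof matrix: nel x 24, dof = 3*(node-1) + comp
element_dofs <- function(elements) {
  nel <- nrow(elements)
  out <- matrix(0L, nel, 24L)
  for (a in 1:8) {
    out[, 3 * a - 2] <- 3L * elements[, a] - 2L
    out[, 3 * a - 1] <- 3L * elements[, a] - 1L
    out[, 3 * a] <- 3L * elements[, a]
  }
  out
}

# sparse global stiffness from per-element lambda/mu (MPa); subset = element
# indices to include
assemble_stiffness <- function(mesh, lam, mu, subset = NULL) {
  edof <- element_dofs(mesh$elements)
  if (!is.null(subset)) {
    edof <- edof[subset, , drop = FALSE]
    lam <- lam[subset]; mu <- mu[subset]
  }
  ndof <- 3L * nrow(mesh$nodes)
  if (nrow(edof) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(ndof, ndof)))
  base <- hex8_base(mesh$edge_length)
  pa <- rep(1:24, times = 24)
  pb <- rep(1:24, each = 24)
  I <- as.vector(edof[, pa])
  J <- as.vector(edof[, pb])
  X <- as.vector(lam %o% as.vector(base$Klam)) +
       as.vector(mu %o% as.vector(base$Kmu))
  Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(ndof, ndof))
}
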