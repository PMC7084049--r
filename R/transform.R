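#' Rigid transform (rotation + translation)
#'
#' Maps physical points `p` (mm) to `rotation %*% p + translation`. The
#' rotation must be proper orthogonal (a pure rotation, no reflection).
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation length-3 numeric vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1L, 3L) else as.matrix(points)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (vec) drop(out) else out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' @rdname apply_transform
#' @param a,b transforms; the result applies `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Least-squares rigid fit from three landmarks
#'
#' Closed-form Kabsch solution: centre both sets, form the cross-covariance,
#' take its SVD and correct any reflection so the rotation is proper. For
#' landmark sets related exactly by a rigid motion the residual is zero to
#' machine precision.
#'
#' @param landmarks_src,landmarks_dst 3 x 3 matrices, one landmark per row
#'   (mm). The fitted transform maps `landmarks_src` onto `landmarks_dst`.
#' @return a `rigid_transform`, with attribute `"rms_residual"` (mm).
#' @export
fit_rigid <- function(landmarks_src, landmarks_dst) {
  src <- as.matrix(landmarks_src)
  dst <- as.matrix(landmarks_dst)
  if (!all(dim(src) == c(3L, 3L)) || !all(dim(dst) == c(3L, 3L)))
    stop("each landmark set must be a 3 x 3 matrix (3 points x 3 coords)")
  check_noncollinear <- function(p, nm) {
    v1 <- p[2, ] - p[1, ]
    v2 <- p[3, ] - p[1, ]
    n <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
    scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
    if (scale == 0 || sqrt(sum(n^2)) < 1e-9 * scale^2)
      stop(sprintf("%s landmarks are collinear or coincident", nm))
  }
  check_noncollinear(src, "source")
  check_noncollinear(dst, "destination")
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cd - drop(R %*% cs)
  tr <- rigid_transform(R, t)
  res <- apply_transform(tr, src) - dst
  attr(tr, "rms_residual") <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Read/write a rigid transform as JSON
#'
#' Stored as 9 row-major rotation entries plus 3 translation entries (mm).
#'
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(transform$rotation)),
         translation = transform$translation),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}

#' Small rotation about an axis through a centre point
#'
#' Convenience constructor used by the phantom generator and tests.
#'
#' @param axis rotation axis (need not be unit length).
#' @param angle_deg rotation angle, degrees.
#' @param centre point the axis passes through, mm.
#' @param translation additional translation applied after rotation, mm.
#' @export
rotation_about <- function(axis, angle_deg, centre = c(0, 0, 0),
                           translation = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t <- centre - drop(R %*% centre) + translation
  rigid_transform(R, t)
}
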