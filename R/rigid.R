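#' Rigid (or similarity) transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @param scale optional uniform scale > 0 (default 1).
#' @return object of class `rigid_transform`. Applying it maps
#'   `x -> scale * R x + t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0) stop("rotation must have determinant +1")
  if (scale <= 0) stop("scale must be positive")
  out <- list(rotation = rotation, translation = as.numeric(translation),
              scale = scale)
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2)))
  cat(sprintf(
    "rigid_transform: rotation %.3f rad, translation (%.2f, %.2f, %.2f) mm, scale %.4f\n",
    ang, x$translation[1], x$translation[2], x$translation[3], x$scale))
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(tf) {
  Rinv <- t(tf$rotation)
  rigid_transform(Rinv, -Rinv %*% tf$translation / tf$scale, 1 / tf$scale)
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x an n x 3 matrix of points or a [tri_mesh()].
#' @param tf a [rigid_transform()].
#' @return the transformed points or mesh (normals rotated, not scaled).
#' @export
apply_transform <- function(x, tf) {
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- apply_transform(x$vertices, tf)
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(tf$rotation)
    return(x)
  }
  pts <- matrix(as.numeric(x), ncol = 3)
  sweep(tf$scale * pts %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Compose two transforms
#'
#' @param tf2,tf1 transforms; the result applies `tf1` first, then `tf2`.
#' @return a [rigid_transform()].
#' @export
compose_transform <- function(tf2, tf1) {
  rigid_transform(tf2$rotation %*% tf1$rotation,
                  tf2$scale * tf2$rotation %*% tf1$translation + tf2$translation,
                  tf2$scale * tf1$scale)
}

#' Uniformly random rotation matrix
#'
#' Drawn via QR decomposition of a Gaussian matrix (Haar measure), using
#' the current RNG state.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Rotation about the z axis
#'
#' @param angle azimuth in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_z <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  rbind(c(c, -s, 0), c(s, c, 0), c(0, 0, 1))
}

#' Weighted Procrustes alignment
#'
#' Closed-form weighted least-squares similarity (or rigid) alignment:
#' finds the transform `T` minimizing `sum_j w_j || T(s_j) - t_j ||^2`
#' over rotations, translations and (optionally) uniform scale. With
#' equal weights and a noiseless similarity-transformed copy the recovery
#' is exact to numerical precision.
#'
#' @param source,target [landmark_set()] objects or n x 3 matrices of
#'   corresponding points.
#' @param weights non-negative weights, one per landmark (default equal).
#' @param scale estimate a uniform scale (default `TRUE`).
#' @return a [rigid_transform()] mapping source onto target.
#' @export
weighted_procrustes <- function(source, target, weights = NULL, scale = TRUE) {
  S <- landmark_positions(source)
  T_ <- landmark_positions(target)
  if (nrow(S) != nrow(T_)) stop("source and target sizes differ")
  n <- nrow(S)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be non-negative, one per landmark")
  pos <- weights > 0
  if (sum(pos) < 3L)
    stop("degenerate configuration: fewer than 3 landmarks with positive weight")
  w <- weights / sum(weights)
  mu_s <- colSums(S * w)
  mu_t <- colSums(T_ * w)
  Sc <- sweep(S, 2, mu_s)
  Tc <- sweep(T_, 2, mu_t)
  sv_s <- svd(Sc * sqrt(w))$d
  if (sum(sv_s > 1e-8 * max(sv_s[1], 1e-300)) < 2L)
    stop("degenerate configuration: collinear support")
  H <- t(Sc * w) %*% Tc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  var_s <- sum(w * rowSums(Sc^2))
  s <- if (scale) sum(sv$d * diag(D)) / var_s else 1
  if (s <= 0) stop("degenerate configuration: non-positive scale")
  t <- mu_t - s * R %*% mu_s
  rigid_transform(R, t, s)
}
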