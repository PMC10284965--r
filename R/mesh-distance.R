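#' Closest points on a reference mesh
#'
#' Exact point-to-triangle projection for a set of query points, with
#' barycentric coordinates and interpolated reference vertex normals at
#' the closest points.
#'
#' @param query numeric q x 3 matrix of query points (mm).
#' @param reference a [tri_mesh()] object.
#' @param normals optional precomputed reference vertex normals.
#' @return list with `points` (closest points), `dist` (unsigned
#'   distances), `tri` (triangle index), `bary` (barycentric coords) and
#'   `normals` (interpolated unit normals at the closest points).
#' @export
closest_points <- function(query, reference, normals = NULL) {
  query <- matrix(as.numeric(query), ncol = 3)
  res <- cpp_closest_on_mesh(query, reference$vertices, reference$faces)
  if (is.null(normals)) {
    normals <- if (!is.null(reference$normals)) reference$normals
               else vertex_normals(reference)
  }
  F <- reference$faces
  tri <- res$tri
  N <- res$bary[, 1] * normals[F[tri, 1], , drop = FALSE] +
       res$bary[, 2] * normals[F[tri, 2], , drop = FALSE] +
       res$bary[, 3] * normals[F[tri, 3], , drop = FALSE]
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N <- N / len
  list(points = res$points, dist = sqrt(pmax(res$dist2, 0)), tri = tri,
       bary = res$bary, normals = N)
}

#' Signed point-to-plane distance field
#'
#' For each (masked) query vertex the distance to the tangent plane at
#' its closest point on the reference surface: `dot(q - c, n_c)` with
#' `n_c` the barycentrically interpolated reference vertex normal. The
#' sign is negative exactly when the query point lies on the inner
#' (tissue) side of the reference surface, i.e. a potential pressure
#' point when the query is a plate.
#'
#' @param query a [tri_mesh()] object (e.g. a plate surface).
#' @param reference a [tri_mesh()] object with usable normals (e.g. the
#'   registered scan).
#' @param mask optional integer vector of query vertex indices.
#' @return an object of class `signed_distance_field`: list with
#'   `distances` (mm, one per masked vertex), `mask`, `mean`, `sd`.
#' @export
signed_point_to_plane_distance <- function(query, reference, mask = NULL) {
  if (is.null(mask)) mask <- seq_len(nrow(query$vertices))
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("empty mask")
  Q <- query$vertices[mask, , drop = FALSE]
  cp <- closest_points(Q, reference)
  d <- rowSums((Q - cp$points) * cp$normals)
  out <- list(distances = d, mask = mask, mean = mean(d), sd = stats::sd(d))
  class(out) <- "signed_distance_field"
  out
}

#' @export
print.signed_distance_field <- function(x, ...) {
  cat(sprintf(
    "signed distance field: n = %d, mean = %.4f mm, sd = %.4f mm, range [%.4f, %.4f]\n",
    length(x$distances), x$mean, x$sd, min(x$distances), max(x$distances)))
  invisible(x)
}

#' Minimum cross distances between point sets
#'
#' For each row of `a`, the minimum Euclidean distance to the rows of `b`.
#'
#' @param a,b numeric matrices with 3 columns.
#' @return numeric vector of length `nrow(a)`.
#' @export
min_cross_distance <- function(a, b) {
  cpp_min_cross_dist(matrix(as.numeric(a), ncol = 3),
                     matrix(as.numeric(b), ncol = 3))
}
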