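#' Mesh primitives
#'
#' Small exact meshes used in examples and tests: a unit tetrahedron, an
#' axis-aligned cube, a regular-grid plane patch, and an icosphere.
#'
#' @param size cube edge length (mm).
#' @param center 3-vector, center of the cube or sphere.
#' @return a [tri_mesh()] object.
#' @name mesh_primitives
NULL

#' @rdname mesh_primitives
#' @export
mesh_tetrahedron <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  F <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  orient_mesh(tri_mesh(V, F))
}

#' @rdname mesh_primitives
#' @export
mesh_cube <- function(size = 1, center = c(0, 0, 0)) {
  g <- expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5), z = c(-0.5, 0.5))
  V <- as.matrix(g) * size
  V <- sweep(V, 2, center, "+")
  # 12 triangles over the 6 faces (indices into the expand.grid order)
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6))   # x = hi
  orient_mesh(tri_mesh(V, F))
}

#' @rdname mesh_primitives
#' @param nx,ny grid resolution of the plane patch.
#' @param width,height plane extents (mm).
#' @export
mesh_plane <- function(nx = 10, ny = 10, width = 10, height = 10) {
  xs <- seq(-width / 2, width / 2, length.out = nx)
  ys <- seq(-height / 2, height / 2, length.out = ny)
  V <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  F <- matrix(0L, 2L * (nx - 1L) * (ny - 1L), 3L)
  r <- 1L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      F[r, ] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
      F[r + 1L, ] <- c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      r <- r + 2L
    }
  }
  tri_mesh(V, F)  # normals along +z
}

#' @rdname mesh_primitives
#' @param subdiv number of icosahedron subdivision rounds (>= 0).
#' @param radius sphere radius (mm).
#' @export
mesh_icosphere <- function(subdiv = 2, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env(hash = TRUE)
    newV <- V
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      got <- mid[[k]]
      if (!is.null(got)) return(got)
      p <- (newV[a, ] + newV[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newV <<- rbind(newV, p)
      idx <- nrow(newV)
      mid[[k]] <- idx
      idx
    }
    newF <- matrix(0L, 0L, 3L)
    for (r in seq_len(nrow(F))) {
      a <- F[r, 1]; b <- F[r, 2]; c <- F[r, 3]
      ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    V <- newV
    F <- newF
  }
  V <- V * radius
  V <- sweep(V, 2, center, "+")
  orient_mesh(tri_mesh(V, F))
}
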