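#' Triangle surface mesh
#'
#' Constructs a validated triangle mesh, the universal surface
#' representation used throughout the package (scans, templates, plates).
#' Coordinates are in millimetres.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, one-based vertex indices.
#' @param normals optional numeric matrix, n x 3, unit vertex normals.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and optionally `normals`.
#' @examples
#' m <- mesh_tetrahedron()
#' m
#' @export
tri_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
          faces[, 2] == faces[, 3]))
    stop("a face references the same vertex twice")
  m <- list(vertices = vertices, faces = faces)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(vertices)))
      stop("normals must match vertices in dimension")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("vertex normals must have unit length")
    m$normals <- normals
  }
  class(m) <- "triangle_mesh"
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$normals)) "" else ", with normals"))
  cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Per-face normals and areas
#'
#' @param mesh a `triangle_mesh`.
#' @return list with `normals` (m x 3 unit vectors, zero rows for
#'   degenerate faces) and `areas` (mm^2).
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(cr^2))
  n <- cr / ifelse(a2 > 0, a2, 1)
  list(normals = n, areas = a2 / 2)
}

#' Area-weighted vertex normals
#'
#' Accumulates face normals weighted by face area. For closed meshes the
#' winding determines the orientation (use [orient_mesh()] to make it
#' outward); palate scans produced by this package are wound so that
#' normals point away from the tissue, into the mouth cavity, which makes
#' the signed point-to-plane distance negative exactly for penetration.
#'
#' @param mesh a `triangle_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  N <- matrix(0, nrow(V), 3)
  w <- fn$normals * fn$areas
  for (k in 1:3) {
    for (j in 1:3) {
      N[, j] <- N[, j] + unname(tapply2(w[, j], F[, k], nrow(V)))
    }
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

# fast grouped sum onto 1..n
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Edge list of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return list with `edges` (unique undirected edges, e x 2, i < j) and
#'   `counts` (number of incident faces per edge).
#' @export
mesh_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  first <- !duplicated(key)
  eu <- cbind(pmin(e[first, 1], e[first, 2]), pmax(e[first, 1], e[first, 2]))
  counts <- as.integer(tab[key[first]])
  list(edges = eu, counts = counts)
}

#' Boundary vertices of an open mesh
#'
#' A vertex is on the boundary if it touches an edge with exactly one
#' incident face.
#'
#' @param mesh a `triangle_mesh`.
#' @return integer vector of boundary vertex indices (possibly empty).
#' @export
boundary_vertices <- function(mesh) {
  ed <- mesh_edges(mesh)
  be <- ed$edges[ed$counts == 1L, , drop = FALSE]
  sort(unique(as.vector(be)))
}

# boundary edges as an e x 2 matrix
boundary_edges <- function(mesh) {
  ed <- mesh_edges(mesh)
  ed$edges[ed$counts == 1L, , drop = FALSE]
}

#' Boundary loops of an open mesh
#'
#' Traces closed cycles of boundary edges.
#'
#' @param mesh a `triangle_mesh`.
#' @return list of integer vectors, each an ordered vertex cycle.
#' @export
boundary_loops <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L) return(list())
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (r in seq_len(nrow(be))) {
    k0 <- ekey(be[r, 1], be[r, 2])
    if (!is.null(used[[k0]])) next
    loop <- c(be[r, 1], be[r, 2])
    used[[k0]] <- TRUE
    repeat {
      cur <- loop[length(loop)]
      nxts <- adj[[as.character(cur)]]
      nxt <- NA
      for (cand in nxts) {
        k <- ekey(cur, cand)
        if (is.null(used[[k]])) {
          nxt <- cand
          used[[k]] <- TRUE
          break
        }
      }
      if (is.na(nxt)) break
      if (nxt == loop[1]) break
      loop <- c(loop, nxt)
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Vertex adjacency list
#'
#' @param mesh a `triangle_mesh`.
#' @return list of integer vectors; element i holds the one-ring
#'   neighbours of vertex i.
#' @export
vertex_adjacency <- function(mesh) {
  ed <- mesh_edges(mesh)$edges
  n <- n_vertices(mesh)
  adj <- split(c(ed[, 2], ed[, 1]), factor(c(ed[, 1], ed[, 2]), levels = 1:n))
  lapply(adj, as.integer)
}

#' Connected components of a vertex subset
#'
#' Components of the subgraph induced by `subset` on the mesh edge graph.
#'
#' @param mesh a `triangle_mesh`.
#' @param subset integer vector of vertex indices (default all).
#' @return integer vector of component labels (named by vertex index).
#' @export
vertex_components <- function(mesh, subset = seq_len(n_vertices(mesh))) {
  ed <- mesh_edges(mesh)$edges
  keep <- ed[, 1] %in% subset & ed[, 2] %in% subset
  ed <- ed[keep, , drop = FALSE]
  idx <- match(subset, subset)
  comp <- seq_along(subset)
  names(comp) <- subset
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  a <- match(ed[, 1], subset)
  b <- match(ed[, 2], subset)
  for (r in seq_along(a)) {
    ra <- find(a[r])
    rb <- find(b[r])
    if (ra != rb) comp[ra] <- rb
  }
  roots <- vapply(seq_along(subset), find, integer(1))
  labels <- match(roots, unique(roots))
  names(labels) <- subset
  labels
}

#' Apply a function-preserving submesh extraction
#'
#' Keeps the faces whose three vertices all belong to `vertices`, dropping
#' unreferenced vertices and remapping indices.
#'
#' @param mesh a `triangle_mesh`.
#' @param vertices integer vector of vertex indices to keep.
#' @return list with `mesh` (the submesh) and `vertex_map` (original index
#'   of each kept vertex).
#' @export
submesh <- function(mesh, vertices) {
  keepv <- sort(unique(as.integer(vertices)))
  inset <- logical(n_vertices(mesh))
  inset[keepv] <- TRUE
  F <- mesh$faces
  fk <- inset[F[, 1]] & inset[F[, 2]] & inset[F[, 3]]
  Fk <- F[fk, , drop = FALSE]
  used <- sort(unique(as.vector(Fk)))
  map <- integer(n_vertices(mesh))
  map[used] <- seq_along(used)
  m <- tri_mesh(mesh$vertices[used, , drop = FALSE],
                cbind(map[Fk[, 1]], map[Fk[, 2]], map[Fk[, 3]]))
  list(mesh = m, vertex_map = used, face_keep = which(fk))
}

#' Flip face orientation
#'
#' @param mesh a `triangle_mesh`.
#' @return the mesh with reversed winding (and flipped stored normals).
#' @export
flip_mesh <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  if (!is.null(mesh$normals)) mesh$normals <- -mesh$normals
  mesh
}

#' Orient a mesh consistently
#'
#' Greedily propagates a consistent winding across face-adjacency and, for
#' closed meshes, flips globally so the enclosed signed volume is positive
#' (outward normals).
#'
#' @param mesh a `triangle_mesh`.
#' @return the reoriented mesh.
#' @export
orient_mesh <- function(mesh) {
  F <- mesh$faces
  m <- nrow(F)
  # adjacency over undirected edges
  ekeys <- function(F) {
    e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  keys <- ekeys(F)
  fid <- rep(seq_len(m), 3L)
  byedge <- split(fid, keys)
  visited <- logical(m)
  flipped <- logical(m)
  for (seed in seq_len(m)) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue)) {
      f <- queue[[1]]
      queue <- queue[-1]
      tri <- F[f, ]
      if (flipped[f]) tri <- tri[c(1, 3, 2)]
      dir_edges <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
      for (r in 1:3) {
        a <- dir_edges[r, 1]; b <- dir_edges[r, 2]
        k <- paste(min(a, b), max(a, b))
        for (g in byedge[[k]]) {
          if (g == f || visited[g]) next
          trig <- F[g, ]
          if (flipped[g]) trig <- trig[c(1, 3, 2)]
          ge <- rbind(trig[c(1, 2)], trig[c(2, 3)], trig[c(3, 1)])
          same <- any(ge[, 1] == a & ge[, 2] == b)
          # consistent orientation means the shared edge runs opposite ways
          if (same) flipped[g] <- TRUE
          visited[g] <- TRUE
          queue <- c(queue, g)
        }
      }
    }
  }
  if (any(flipped)) {
    F[flipped, ] <- F[flipped, c(1, 3, 2), drop = FALSE]
    mesh$faces <- F
    mesh$normals <- NULL
  }
  if (length(boundary_vertices(mesh)) == 0L && signed_volume(mesh) < 0)
    mesh <- flip_mesh(mesh)
  mesh
}

#' Signed volume enclosed by a mesh
#'
#' Sum of signed tetrahedron volumes against the origin; meaningful for
#' closed, consistently oriented meshes (positive when normals point
#' outward).
#'
#' @param mesh a `triangle_mesh`.
#' @return volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Edge length statistics
#'
#' @param mesh a `triangle_mesh`.
#' @return named numeric vector with `mean`, `max` and `min` edge length (mm).
#' @export
edge_lengths <- function(mesh) {
  ed <- mesh_edges(mesh)$edges
  d <- sqrt(rowSums((mesh$vertices[ed[, 1], , drop = FALSE] -
                     mesh$vertices[ed[, 2], , drop = FALSE])^2))
  c(mean = mean(d), max = max(d), min = min(d))
}
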