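# independent brute-force oracles used to cross-check the C++ kernels

# segment-triangle proper intersection (Moller-Trumbore)
segment_hits_triangle <- function(p, q, a, b, c, eps = 1e-12) {
  d <- q - p
  e1 <- b - a
  e2 <- c - a
  pv <- c(d[2] * e2[3] - d[3] * e2[2],
          d[3] * e2[1] - d[1] * e2[3],
          d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * pv)
  if (abs(det) < eps) return(FALSE)
  tv <- p - a
  u <- sum(tv * pv) / det
  if (u < eps || u > 1 - eps) return(FALSE)
  qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
          tv[3] * e1[1] - tv[1] * e1[3],
          tv[1] * e1[2] - tv[2] * e1[1])
  v <- sum(d * qv) / det
  if (v < eps || u + v > 1 - eps) return(FALSE)
  t <- sum(e2 * qv) / det
  t > eps && t < 1 - eps
}

# count of non-adjacent triangle pairs with a proper crossing
brute_force_self_intersections <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  nf <- nrow(F)
  count <- 0L
  for (f in seq_len(nf - 1L)) {
    for (g in (f + 1L):nf) {
      if (length(intersect(F[f, ], F[g, ]))) next
      tf <- lapply(1:3, function(k) V[F[f, k], ])
      tg <- lapply(1:3, function(k) V[F[g, k], ])
      hit <- FALSE
      for (e in 1:3) {
        e2 <- e %% 3L + 1L
        if (segment_hits_triangle(tf[[e]], tf[[e2]], tg[[1]], tg[[2]],
                                  tg[[3]]) ||
            segment_hits_triangle(tg[[e]], tg[[e2]], tf[[1]], tf[[2]],
                                  tf[[3]])) {
          hit <- TRUE
          break
        }
      }
      if (hit) count <- count + 1L
    }
  }
  count
}

# brute-force edge incidence: edge key -> number of incident faces
brute_force_edge_counts <- function(mesh) {
  F <- mesh$faces
  keys <- character(0)
  for (f in seq_len(nrow(F))) {
    tri <- F[f, ]
    for (e in 1:3) {
      a <- tri[e]
      b <- tri[e %% 3L + 1L]
      keys <- c(keys, paste(min(a, b), max(a, b)))
    }
  }
  table(keys)
}

# fan disk mesh: centre + ring, used as an analytic volumization fixture
disk_mesh <- function(n = 24, radius = 5, z = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  V <- rbind(c(0, 0, z), cbind(radius * cos(th), radius * sin(th), z))
  F <- cbind(1L, 1L + seq_len(n), 1L + c(2:n, 1L))
  tri_mesh(V, F)
}
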