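#' Mesh quality report
#'
#' Checks watertightness (every edge bounds exactly two faces with
#' consistent winding), counts proper triangle-triangle self-intersections
#' between non-adjacent faces, counts degenerate (zero-area) faces and
#' connected components.
#'
#' @param mesh a [tri_mesh()] object.
#' @return an object of class `mesh_quality_report`: list with
#'   `is_watertight`, `self_intersection_count`, `degenerate_face_count`,
#'   `n_components`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  F <- mesh$faces
  ed <- mesh_edges(mesh)
  closed <- all(ed$counts == 2L)
  consistent <- TRUE
  if (closed) {
    # each directed edge must appear exactly once
    de <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    key <- paste(de[, 1], de[, 2])
    consistent <- !anyDuplicated(key)
  }
  areas <- face_normals(mesh)$areas
  degen <- sum(areas < 1e-12)
  comp <- vertex_components(mesh)
  rep <- list(
    is_watertight = closed && consistent,
    self_intersection_count = cpp_self_intersections(mesh$vertices, F),
    degenerate_face_count = as.integer(degen),
    n_components = max(comp)
  )
  class(rep) <- "mesh_quality_report"
  rep
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat("mesh quality report\n")
  cat("  watertight:          ", x$is_watertight, "\n")
  cat("  self-intersections:  ", x$self_intersection_count, "\n")
  cat("  degenerate faces:    ", x$degenerate_face_count, "\n")
  cat("  connected components:", x$n_components, "\n")
  invisible(x)
}
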