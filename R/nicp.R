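#' Configuration for nonrigid ICP registration
#'
#' Amberg-style optimal-step nonrigid ICP: per-vertex 3x4 affine
#' transforms minimizing a data + stiffness + landmark energy, solved as
#' a sparse linear least-squares problem per inner iteration while the
#' stiffness is annealed downwards.
#'
#' @param stiffness decreasing positive stiffness schedule.
#' @param landmark_weight landmark-term weight schedule, decreasing to 0
#'   (recycled/truncated to the stiffness schedule length).
#' @param inner_iterations correspondence updates per stiffness step.
#' @param max_dist reject correspondences further than this (mm).
#' @param max_normal_angle reject correspondences whose normals disagree
#'   by more than this angle (degrees).
#' @param reject_boundary reject closest points on the target border.
#' @param gamma weighting of the translation column in the stiffness term.
#' @return object of class `nicp_config`.
#' @export
nicp_config <- function(stiffness = c(50, 20, 5, 2, 0.8),
                        landmark_weight = c(5, 2, 0.5, 0, 0),
                        inner_iterations = 3, max_dist = 5,
                        max_normal_angle = 60, reject_boundary = TRUE,
                        gamma = 1) {
  if (length(stiffness) == 0 || any(stiffness <= 0) ||
      any(diff(stiffness) > 0))
    stop("stiffness schedule must be positive and non-increasing")
  if (any(landmark_weight < 0) || any(diff(landmark_weight) > 0))
    stop("landmark weight schedule must be non-negative and non-increasing")
  lw <- rep(landmark_weight, length.out = length(stiffness))
  structure(list(stiffness = stiffness, landmark_weight = lw,
                 inner_iterations = as.integer(inner_iterations),
                 max_dist = max_dist, max_normal_angle = max_normal_angle,
                 reject_boundary = reject_boundary, gamma = gamma),
            class = "nicp_config")
}

#' Nonrigid iterative closest point registration
#'
#' Deforms `source` onto `target` with one 3x4 affine per source vertex,
#' minimizing the weighted distance of active vertices to their closest
#' compatible points on the target, a graph-arc stiffness penalty on
#' neighbouring affines, and an optional landmark term. Masked-out
#' vertices carry zero data weight but stay stiffness-coupled (this is
#' how the alveolar bridge spans a cleft); pinned vertices retain their
#' prescribed positions exactly (their affine block is eliminated from
#' the system).
#'
#' @param source a [tri_mesh()] (e.g. the template).
#' @param target a [tri_mesh()] (e.g. the scan).
#' @param config a [nicp_config()].
#' @param active logical or integer vector: source vertices with an
#'   active data term (default all).
#' @param landmarks optional list with `source_idx` (vertex indices on
#'   the source), `target` (k x 3 positions) and `weights` (k
#'   non-negative values, e.g. prediction probabilities).
#' @param pinned optional list with `idx` (vertex indices) and
#'   `positions` (matching matrix of prescribed positions).
#' @param trace record per-step mean active point-to-surface residuals.
#' @return the deformed source mesh; with `trace = TRUE` an attribute
#'   `"trace"` holds the residual per stiffness step.
#' @export
nicp <- function(source, target, config = nicp_config(), active = NULL,
                 landmarks = NULL, pinned = NULL, trace = FALSE) {
  n <- n_vertices(source)
  # solve in the source-centroid frame: the affine stiffness term is
  # origin-dependent, so centering makes the result rigid-equivariant
  shift <- colMeans(source$vertices)
  source$vertices <- sweep(source$vertices, 2, shift)
  target <- target
  target$vertices <- sweep(target$vertices, 2, shift)
  if (!is.null(landmarks))
    landmarks$target <- sweep(landmarks$target, 2, shift)
  if (!is.null(pinned) && length(pinned$idx))
    pinned$positions <- sweep(pinned$positions, 2, shift)
  V <- source$vertices
  if (is.null(active)) active <- rep(TRUE, n)
  if (!is.logical(active)) active <- seq_len(n) %in% active
  ed <- mesh_edges(source)$edges
  ne <- nrow(ed)
  g <- c(1, 1, 1, config$gamma)

  # stiffness block K (4*ne x 4n): rows alpha * (block_i - block_j)
  ii <- rep(seq_len(4L * ne), 2L)
  jj <- c(rep((ed[, 1] - 1L) * 4L, each = 4L) + rep(1:4, ne),
          rep((ed[, 2] - 1L) * 4L, each = 4L) + rep(1:4, ne))
  xx <- c(rep(g, ne), -rep(g, ne))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(4L * ne, 4L * n))
  KtK <- Matrix::crossprod(K)

  # data-term design row for vertex i is [v_i, 1] in its 4-column block
  data_rows <- function(idx, w) {
    k <- length(idx)
    Matrix::sparseMatrix(
      i = rep(seq_len(k), each = 4L),
      j = as.vector(vapply(idx, function(i) (i - 1L) * 4L + 1:4,
                           integer(4))),
      x = as.vector(t(cbind(V[idx, , drop = FALSE], 1) * w)),
      dims = c(k, 4L * n))
  }

  pin_idx <- integer(0)
  Xpin <- NULL
  if (!is.null(pinned) && length(pinned$idx)) {
    pin_idx <- as.integer(pinned$idx)
    # prescribed affine: the translation carrying v_p to its pin
    Xpin <- matrix(0, 4L * length(pin_idx), 3L)
    for (k in seq_along(pin_idx)) {
      Xpin[(k - 1L) * 4L + 1:3, ] <- diag(3)
      Xpin[(k - 1L) * 4L + 4L, ] <-
        pinned$positions[k, ] - V[pin_idx[k], ]
    }
  }
  pin_cols <- as.vector(vapply(pin_idx, function(i) (i - 1L) * 4L + 1:4,
                               integer(4)))
  free_cols <- setdiff(seq_len(4L * n), pin_cols)

  # initial affines: identity
  X <- matrix(0, 4L * n, 3L)
  X[seq(1, 4L * n, by = 4L), 1] <- 1
  X[seq(2, 4L * n, by = 4L), 2] <- 1
  X[seq(3, 4L * n, by = 4L), 3] <- 1
  if (length(pin_idx)) X[pin_cols, ] <- Xpin

  tN <- vertex_normals(target)
  tb <- logical(n_vertices(target))
  tb[boundary_vertices(target)] <- TRUE
  cosmax <- cos(config$max_normal_angle * pi / 180)
  Dall <- data_rows(seq_len(n), rep(1, n))
  deform <- function(X) as.matrix(Dall %*% X)

  tr <- numeric(0)
  for (step in seq_along(config$stiffness)) {
    alpha <- config$stiffness[step]
    beta <- config$landmark_weight[step]
    for (it in seq_len(config$inner_iterations)) {
      Y <- deform(X)
      cur <- source
      cur$vertices <- Y
      cur$normals <- NULL
      sN <- vertex_normals(cur)
      cp <- closest_points(Y, target, normals = tN)
      w <- as.numeric(active)
      w[cp$dist > config$max_dist] <- 0
      w[rowSums(sN * cp$normals) < cosmax] <- 0
      if (config$reject_boundary) {
        F <- target$faces
        onb <- (cp$bary[, 1] < 1e-3 | tb[F[cbind(cp$tri, 1)]]) &
               (cp$bary[, 2] < 1e-3 | tb[F[cbind(cp$tri, 2)]]) &
               (cp$bary[, 3] < 1e-3 | tb[F[cbind(cp$tri, 3)]])
        w[onb] <- 0
      }
      idx <- which(w > 0)
      M <- alpha^2 * KtK
      rhs <- Matrix::Matrix(0, 4L * n, 3L)
      if (length(idx)) {
        Dw <- data_rows(idx, w[idx])
        M <- M + Matrix::crossprod(Dw)
        rhs <- rhs + Matrix::crossprod(Dw, w[idx] * cp$points[idx, ,
                                                             drop = FALSE])
      }
      if (!is.null(landmarks) && beta > 0) {
        lw <- beta * landmarks$weights
        keep <- lw > 0
        if (any(keep)) {
          Dl <- data_rows(landmarks$source_idx[keep], lw[keep])
          M <- M + Matrix::crossprod(Dl)
          rhs <- rhs + Matrix::crossprod(
            Dl, lw[keep] * landmarks$target[keep, , drop = FALSE])
        }
      }
      if (length(pin_idx)) {
        rhs_f <- rhs[free_cols, , drop = FALSE] -
          M[free_cols, pin_cols, drop = FALSE] %*% Xpin
        Mf <- M[free_cols, free_cols, drop = FALSE]
      } else {
        rhs_f <- rhs
        Mf <- M
      }
      Xf <- tryCatch(
        as.matrix(Matrix::solve(Matrix::forceSymmetric(Mf), rhs_f)),
        error = function(e)
          stop("singular system: a component has no data term or pins"))
      X[free_cols, ] <- Xf
      if (length(pin_idx)) X[pin_cols, ] <- Xpin
    }
    if (trace) {
      Y <- deform(X)
      cp <- closest_points(Y[active, , drop = FALSE], target, normals = tN)
      tr <- c(tr, mean(cp$dist))
    }
  }
  out <- source
  out$vertices <- sweep(deform(X), 2, shift, "+")
  out$normals <- NULL
  if (trace) attr(out, "trace") <- tr
  out
}
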