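# Laplacian smoothing of per-vertex quantities (matrix of columns)
smooth_vertex_field <- function(X, adj, passes, damping = 0.5) {
  X <- as.matrix(X)
  for (s in seq_len(passes)) {
    M <- X
    for (j in seq_len(ncol(X))) {
      mj <- vapply(adj, function(nb) mean(X[nb, j]), 0)
      M[, j] <- X[, j] + damping * (mj - X[, j])
    }
    X <- M
  }
  X
}

# rotation-canonical PCA frame: centered coordinates expressed in the
# principal axes, axis signs fixed by the third moment (skewness) of the
# projections, handedness fixed last
canonical_coords <- function(V) {
  C <- sweep(V, 2, colMeans(V))
  ev <- eigen(crossprod(C) / nrow(C), symmetric = TRUE)
  P <- C %*% ev$vectors
  sk <- colSums(P^3)
  sgn <- ifelse(sk < 0, -1, 1)
  P <- sweep(P, 2, sgn, "*")
  A <- sweep(ev$vectors, 2, sgn, "*")
  if (det(A) < 0) {
    k <- which.min(abs(sk))
    P[, k] <- -P[, k]
  }
  P
}

# per-vertex feature matrix for the landmark scorer
mesh_features <- function(mesh, stage) {
  V <- mesh$vertices
  adj <- vertex_adjacency(mesh)
  N <- vertex_normals(mesh)
  P <- if (stage == 1L) canonical_coords(V) else sweep(V, 2, colMeans(V))
  lap <- smooth_vertex_field(P, adj, 1, damping = 1) - P
  # curvature proxy: rotation-invariant magnitude for stage 1, signed
  # normal component for stage 2
  curv <- if (stage == 1L) sqrt(rowSums(lap^2)) else rowSums(lap * N)
  S3 <- smooth_vertex_field(P, adj, 3)
  S10 <- smooth_vertex_field(P, adj, 10)
  curv5 <- smooth_vertex_field(matrix(curv), adj, 5)
  cbind(1, P, rowSums(P^2) / 100, S3, S10, curv, curv5)
}

#' Train a per-vertex landmark scorer
#'
#' Fits the reference backbone: a ridge-regression scorer over multi-scale
#' geometric vertex features (principal-frame or aligned coordinates,
#' Laplacian-smoothed coordinates at several scales, curvature proxies),
#' trained with the mean squared error against the exponential proximity
#' target maps of [build_target_maps()]. Stage 1 augments each training
#' mesh with uniformly random 3D rotations and uses rotation-canonical
#' features, so arbitrarily oriented meshes can be scored; stage 2 is
#' trained on aligned meshes augmented only over a limited azimuthal
#' range of +/- 0.2 rad about the z axis, which makes it the more precise
#' second pass. The dataset is split 80/20 into train/test by the seed.
#'
#' @param dataset list of `palate_scan` objects, or of lists with
#'   elements `mesh` and `landmarks`.
#' @param stage 1 (arbitrary orientation) or 2 (near-aligned).
#' @param seed integer seed; training is reproducible given the seed.
#' @param n_augment rotation augmentations per mesh (default 4).
#' @param lambda ridge penalty (relative; default 1e-6).
#' @return object of class `palate_predictor` with the fitted weights and
#'   metadata (`stage`, `seed`, `augment_angles` for stage 2, train/test
#'   MSE).
#' @export
train_predictor <- function(dataset, stage, seed = 1, n_augment = 4,
                            lambda = 1e-6) {
  if (length(dataset) < 2L)
    stop("dataset too small to split into train and test")
  stage <- as.integer(stage)
  stopifnot(stage %in% c(1L, 2L))
  with_seed(seed, {
    ord <- sample(length(dataset))
    ntrain <- max(1L, floor(0.8 * length(dataset)))
    train_idx <- ord[seq_len(ntrain)]
    test_idx <- ord[-seq_len(ntrain)]
    XtX <- NULL
    XtY <- NULL
    angles <- numeric(0)
    for (i in train_idx) {
      d <- dataset[[i]]
      for (a in seq_len(n_augment)) {
        if (stage == 1L) {
          Rm <- random_rotation()
        } else {
          az <- stats::runif(1, -0.2, 0.2)
          angles <- c(angles, az)
          Rm <- rotation_z(az)
        }
        tf <- rigid_transform(Rm)
        mesh <- apply_transform(d$mesh, tf)
        lm <- landmark_set(apply_transform(d$landmarks$positions, tf))
        X <- mesh_features(mesh, stage)
        Y <- build_target_maps(mesh, lm)$scores
        if (is.null(XtX)) {
          XtX <- crossprod(X)
          XtY <- crossprod(X, Y)
        } else {
          XtX <- XtX + crossprod(X)
          XtY <- XtY + crossprod(X, Y)
        }
      }
    }
    W <- solve(XtX + lambda * mean(diag(XtX)) * diag(nrow(XtX)), XtY)
  })
  pred <- structure(
    list(type = "ridge", stage = stage, weights = W, seed = seed,
         n_augment = n_augment,
         augment_spec = if (stage == 1L) "uniform random 3D rotations"
                        else "azimuth about z in [-0.2, 0.2] rad",
         augment_angles = if (stage == 2L) angles else NULL),
    class = "palate_predictor")
  pred$train_mse <- predictor_mse(pred, dataset[train_idx])
  pred$test_mse <- if (length(test_idx))
    predictor_mse(pred, dataset[test_idx]) else NA_real_
  pred
}

#' Oracle landmark scorer
#'
#' A predictor that reproduces the exact target maps from ground-truth
#' landmarks supplied at prediction time; it makes the geometric pipeline
#' testable without any training.
#'
#' @param stage 1 or 2.
#' @return a `palate_predictor` of type `"oracle"`.
#' @export
oracle_predictor <- function(stage = 1) {
  structure(list(type = "oracle", stage = as.integer(stage)),
            class = "palate_predictor")
}

#' @export
print.palate_predictor <- function(x, ...) {
  if (x$type == "oracle") {
    cat(sprintf("palate_predictor: oracle, stage %d\n", x$stage))
  } else {
    cat(sprintf(
      "palate_predictor: ridge scorer, stage %d (%s), train MSE %.3g, test MSE %.3g\n",
      x$stage, x$augment_spec, x$train_mse, x$test_mse))
  }
  invisible(x)
}

#' Score a mesh with a landmark predictor
#'
#' @param object a `palate_predictor`.
#' @param mesh a [tri_mesh()] to score.
#' @param landmarks ground-truth [landmark_set()], required by oracle
#'   predictors and ignored otherwise.
#' @param ... unused.
#' @return raw [segmentation_maps()] (one column per landmark).
#' @export
predict.palate_predictor <- function(object, mesh, landmarks = NULL, ...) {
  if (object$type == "oracle") {
    if (is.null(landmarks))
      stop("oracle predictor needs ground-truth landmarks")
    maps <- build_target_maps(mesh, landmarks)
    return(segmentation_maps(maps$scores, normalized = FALSE))
  }
  X <- mesh_features(mesh, object$stage)
  segmentation_maps(X %*% object$weights, normalized = FALSE)
}

#' Mean squared error of a predictor against its proximity targets
#'
#' @param predictor a `palate_predictor`.
#' @param dataset list of scans with `mesh` and `landmarks`.
#' @return mean squared error over all vertices, landmarks and scans.
#' @export
predictor_mse <- function(predictor, dataset) {
  se <- 0
  n <- 0
  for (d in dataset) {
    Y <- build_target_maps(d$mesh, d$landmarks)$scores
    P <- predict(predictor, d$mesh, landmarks = d$landmarks)$scores
    se <- se + sum((P - Y)^2)
    n <- n + length(Y)
  }
  se / n
}

#' Two-stage landmark prediction with Procrustes realignment
#'
#' Stage 1 scores the arbitrarily oriented input mesh and its landmarks
#' are extracted with certainties P1; a weighted Procrustes fit of those
#' landmarks onto the template landmarks (weighted by P1) aligns the mesh
#' with the template; stage 2 then scores the aligned mesh for the more
#' accurate final prediction with certainties P2. If the weighted fit is
#' degenerate an unweighted fit is tried before giving up.
#'
#' @param mesh a [tri_mesh()] scan in arbitrary orientation.
#' @param stage1,stage2 `palate_predictor` objects for stages 1 and 2.
#' @param template a `palate_template` providing the landmark set the
#'   alignment targets.
#' @param landmarks ground-truth [landmark_set()] for oracle predictors.
#' @return list with `landmarks` (a [landmark_set()] with probabilities
#'   P2, in the aligned/template frame), `alignment` (the
#'   [rigid_transform()] mapping the input into the template frame),
#'   `aligned_mesh`, and `stage1_landmarks`.
#' @export
predict_two_stage <- function(mesh, stage1, stage2, template,
                              landmarks = NULL) {
  maps1 <- predict(stage1, mesh, landmarks = landmarks)
  lp1 <- extract_landmarks(maps1, mesh)
  tf <- tryCatch(
    weighted_procrustes(lp1, template$landmarks, weights = lp1$probabilities),
    error = function(e)
      tryCatch(weighted_procrustes(lp1, template$landmarks),
               error = function(e2)
                 stop("degenerate landmark configuration for alignment")))
  aligned <- apply_transform(mesh, tf)
  lm2 <- if (!is.null(landmarks))
    landmark_set(apply_transform(landmarks$positions, tf),
                 landmarks$probabilities)
  maps2 <- predict(stage2, aligned, landmarks = lm2)
  lp2 <- extract_landmarks(maps2, aligned)
  list(landmarks = lp2, alignment = tf, aligned_mesh = aligned,
       stage1_landmarks = lp1)
}
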