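#' The ten palatal landmark names
#'
#' Fixed landmark identities used by the synthetic generator, the
#' templates and the landmarking pipeline: the posterior ends and
#' midpoints of the left/right alveolar ridges, the two anterior cleft
#' margins, the anterior (premaxilla) and posterior midline points, and
#' two posterior cleft-palate margin points.
#'
#' @return character vector of length 10.
#' @export
palate_landmark_names <- function() {
  c("ridge_post_L", "ridge_post_R", "ridge_mid_L", "ridge_mid_R",
    "cleft_margin_ant_L", "cleft_margin_ant_R", "midline_ant",
    "midline_post", "cleft_margin_post_L", "cleft_margin_post_R")
}

#' Named landmark set
#'
#' @param positions 10 x 3 numeric matrix of 3D positions (mm), rows
#'   named; unnamed rows get [palate_landmark_names()].
#' @param probabilities optional per-landmark prediction probabilities in
#'   `[0, 1]`.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(positions, probabilities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be n x 3")
  if (nrow(positions) != 10L) stop("a landmark set has exactly 10 landmarks")
  if (!all(is.finite(positions))) stop("landmark positions must be finite")
  if (is.null(rownames(positions))) rownames(positions) <- palate_landmark_names()
  colnames(positions) <- c("x", "y", "z")
  out <- list(names = rownames(positions), positions = positions)
  if (!is.null(probabilities)) {
    probabilities <- as.numeric(probabilities)
    if (length(probabilities) != 10L)
      stop("probabilities must have one entry per landmark")
    if (any(probabilities < 0 | probabilities > 1))
      stop("probabilities must lie in [0, 1]")
    out$probabilities <- probabilities
  }
  class(out) <- "landmark_set"
  out
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set (10 landmarks)\n")
  df <- data.frame(round(x$positions, 3))
  colnames(df) <- c("x", "y", "z")
  if (!is.null(x$probabilities)) df$prob <- round(x$probabilities, 3)
  print(df)
  invisible(x)
}

landmark_positions <- function(x) {
  if (inherits(x, "landmark_set")) x$positions else matrix(as.numeric(x), ncol = 3)
}

#' Per-vertex segmentation maps
#'
#' A vertex x landmark score matrix; the prediction target and output of
#' the landmark scorer.
#'
#' @param scores numeric n x 10 matrix, one column per landmark.
#' @param normalized logical; `TRUE` when scores are guaranteed in `[0, 1]`.
#' @return object of class `segmentation_maps`.
#' @export
segmentation_maps <- function(scores, normalized = FALSE) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 10L) stop("segmentation maps have 10 columns")
  if (is.null(colnames(scores))) colnames(scores) <- palate_landmark_names()
  if (normalized && length(scores) &&
      (min(scores) < -1e-12 || max(scores) > 1 + 1e-12))
    stop("normalized scores must lie in [0, 1]")
  out <- list(scores = scores, normalized = normalized)
  class(out) <- "segmentation_maps"
  out
}

#' @export
print.segmentation_maps <- function(x, ...) {
  cat(sprintf("segmentation_maps: %d vertices x %d landmarks (%s)\n",
              nrow(x$scores), ncol(x$scores),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Exponential proximity target maps
#'
#' The per-vertex regression target for landmark j at vertex i is the
#' continuous exponential fall-off `exp(-0.5 * ||l_j - v_i||)` with
#' distances in mm, a smooth artificial probability map peaking at 1 on
#' the landmark itself.
#'
#' @param mesh a [tri_mesh()] object.
#' @param landmarks a [landmark_set()].
#' @return normalized [segmentation_maps()].
#' @export
build_target_maps <- function(mesh, landmarks) {
  L <- landmark_positions(landmarks)
  V <- mesh$vertices
  S <- matrix(0, nrow(V), nrow(L))
  for (j in seq_len(nrow(L))) {
    d <- sqrt((V[, 1] - L[j, 1])^2 + (V[, 2] - L[j, 2])^2 +
              (V[, 3] - L[j, 3])^2)
    S[, j] <- exp(-0.5 * d)
  }
  colnames(S) <- rownames(L)
  segmentation_maps(S, normalized = TRUE)
}

#' Clamp raw maps and read per-landmark certainties
#'
#' Raw predictor output is clamped to `[0, 1]`; the certainty of landmark
#' j is the clamped score at its argmax vertex. (Clamping, rather than
#' per-column min-max scaling, keeps the peak magnitude informative.)
#'
#' @param raw_maps [segmentation_maps()] with raw scores.
#' @return list with `maps` (normalized [segmentation_maps()]) and
#'   `certainty` (length-10 vector in `[0, 1]`).
#' @export
normalize_certainty <- function(raw_maps) {
  S <- raw_maps$scores
  if (!all(is.finite(S))) stop("raw maps must be finite")
  Sc <- S
  Sc[Sc < 0] <- 0
  Sc[Sc > 1] <- 1
  arg <- apply(S, 2, which.max)
  cert <- Sc[cbind(arg, seq_len(ncol(Sc)))]
  list(maps = segmentation_maps(Sc, normalized = TRUE), certainty = cert)
}

#' Extract landmark positions from segmentation maps
#'
#' Landmark j is placed on the argmax vertex of column j (ties broken by
#' the lowest vertex index); probabilities are the clamped peak scores.
#'
#' @param maps a [segmentation_maps()] object (raw or normalized).
#' @param mesh the mesh the maps were computed on.
#' @return a [landmark_set()] with probabilities, plus attribute
#'   `"vertex"` holding the argmax vertex indices.
#' @export
extract_landmarks <- function(maps, mesh) {
  S <- maps$scores
  if (nrow(S) == 0L) stop("empty segmentation maps")
  if (nrow(S) != nrow(mesh$vertices))
    stop("maps row count must equal the vertex count")
  nc <- normalize_certainty(maps)
  arg <- apply(S, 2, which.max)  # which.max takes the first (lowest) index
  pos <- mesh$vertices[arg, , drop = FALSE]
  rownames(pos) <- colnames(S)
  out <- landmark_set(pos, probabilities = nc$certainty)
  attr(out, "vertex") <- arg
  out
}
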