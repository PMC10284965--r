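#' Region-staged template-to-scan registration
#'
#' Registers a labeled template onto an (aligned) scan in two NICP
#' cycles, following the plate-oriented staging: cycle 1 deforms only the
#' alveolar ridges (data term active on ridge-labeled vertices, landmark
#' term weighted by the prediction probabilities P2), shifting the focus
#' to the plate's contact region; cycle 2 registers the remaining regions
#' with the ridge vertices pinned at their cycle-1 positions and no
#' landmark term. Vertices labeled `bridge` (the annotated alveolar-cleft
#' sector of the healthy-ridge template) carry no data term in either
#' cycle but remain stiffness-coupled, so the registered ridge spans the
#' scan's cleft gap like a healthy ridge.
#'
#' Because the template topology is preserved, the scan is effectively
#' resampled at the template's resolution and the template's region
#' labels segment the registered scan.
#'
#' @param template a `palate_template` (see [generate_template()]).
#' @param scan a [tri_mesh()] roughly aligned with the template (e.g. via
#'   [predict_two_stage()]).
#' @param landmarks a [landmark_set()] with probabilities (P2), in the
#'   same frame as `scan`; optional.
#' @param config a [nicp_config()].
#' @return object of class `registered_scan`: list with `mesh` (deformed
#'   template), `labels`, `template`, `scan`, `active1`/`active2` masks
#'   and `landmark_pairs`.
#' @export
staged_register <- function(template, scan, landmarks = NULL,
                            config = nicp_config()) {
  stopifnot(inherits(template, "palate_template"))
  lab <- template$labels
  ridge <- lab == "alveolar_ridge"
  bridge <- lab == "bridge"
  lm <- NULL
  if (!is.null(landmarks)) {
    src_idx <- apply(template$landmarks$positions, 1, function(l) {
      which.min(colSums((t(template$mesh$vertices) - l)^2))
    })
    wts <- landmarks$probabilities
    if (is.null(wts)) wts <- rep(1, 10)
    lm <- list(source_idx = as.integer(src_idx),
               target = landmarks$positions, weights = wts)
  }
  cycle1 <- nicp(template$mesh, scan, config = config, active = ridge,
                 landmarks = lm)
  cfg2 <- config
  cfg2$landmark_weight <- rep(0, length(config$stiffness))
  active2 <- !(ridge | bridge)
  pin <- list(idx = which(ridge),
              positions = cycle1$vertices[ridge, , drop = FALSE])
  cycle2 <- nicp(cycle1, scan, config = cfg2, active = active2,
                 pinned = pin)
  out <- list(mesh = cycle2, labels = lab, template = template, scan = scan,
              active1 = ridge, active2 = active2,
              landmark_pairs = lm)
  class(out) <- "registered_scan"
  out
}

#' @export
print.registered_scan <- function(x, ...) {
  d <- closest_points(x$mesh$vertices[x$active1, , drop = FALSE], x$scan)$dist
  cat(sprintf(
    "registered_scan: %d vertices (template topology), ridge residual %.3f mm (mean)\n",
    nrow(x$mesh$vertices), mean(d)))
  invisible(x)
}

#' Segmentation of the registered (resampled) scan
#'
#' The template's pre-segmented regions represent the corresponding scan
#' structures after registration; since the topology is preserved the
#' labels transfer by vertex identity.
#'
#' @param registered a `registered_scan`.
#' @return factor of per-vertex labels over [palate_region_names()].
#' @export
transfer_segmentation <- function(registered) {
  stopifnot(inherits(registered, "registered_scan"))
  registered$labels
}

#' Segment the raw scan via dense correspondence
#'
#' Labels each scan vertex with the region of its nearest registered
#' template vertex (used e.g. to identify the cleft-tissue vertices the
#' plate must keep clear of).
#'
#' @param registered a `registered_scan`.
#' @return factor of labels, one per scan vertex.
#' @export
segment_scan <- function(registered) {
  stopifnot(inherits(registered, "registered_scan"))
  cp <- closest_points(registered$scan$vertices, registered$mesh)
  F <- registered$mesh$faces
  # label of the dominant barycentric corner of the closest triangle
  corner <- max.col(cp$bary)
  vid <- F[cbind(cp$tri, corner)]
  registered$labels[vid]
}
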