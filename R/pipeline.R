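#' Compute a presurgical orthopedic plate from a palate scan
#'
#' Runs the full pipeline: two-stage landmarking, Procrustes alignment to
#' the template, region-staged NICP registration (with alveolar-cleft
#' bridging for UCLP), plate-area cutting, sphere-based cleft filling,
#' curvature-selective smoothing, contact and outer offsetting, and
#' watertight volumization. All geometry is computed in the template
#' (aligned) frame; the alignment transform is returned so results can be
#' mapped back to the input pose.
#'
#' @param scan a `palate_scan` (synthetic, with ground truth) or a
#'   [tri_mesh()].
#' @param template a `palate_template` of the matching cleft type.
#' @param stage1,stage2 `palate_predictor` objects (default oracle
#'   predictors, which require ground-truth landmarks: either a
#'   `palate_scan` input or `truth_landmarks`).
#' @param truth_landmarks optional [landmark_set()] for oracle
#'   predictors when `scan` is a bare mesh.
#' @param nicp a [nicp_config()].
#' @param plate a [plate_params()].
#' @return object of class `plate_fit` with elements `plate` (a
#'   `palate_plate`), `registered`, `alignment`, `landmarks`, `manifest`.
#' @examples
#' \donttest{
#' tpl <- generate_template("UCLP", n_samples = 3, seed = 1)
#' scan <- generate_palate(palate_params("UCLP", seed = 7))
#' fit <- compute_plate(scan, tpl)
#' fit
#' }
#' @export
compute_plate <- function(scan, template, stage1 = oracle_predictor(1),
                          stage2 = oracle_predictor(2),
                          truth_landmarks = NULL, nicp = nicp_config(),
                          plate = plate_params()) {
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  truth <- truth_landmarks
  labels_truth <- NULL
  if (inherits(scan, "palate_scan")) {
    truth <- if (is.null(truth)) scan$landmarks else truth
    labels_truth <- scan$labels
    scan <- scan$mesh
  }
  t0 <- tic()
  pred <- predict_two_stage(scan, stage1, stage2, template,
                            landmarks = truth)
  timings["landmark"] <- tic() - t0

  t0 <- tic()
  reg <- staged_register(template, pred$aligned_mesh,
                         landmarks = pred$landmarks, config = nicp)
  timings["register"] <- tic() - t0

  t0 <- tic()
  cut <- cut_plate_area(reg)
  if (!is.null(labels_truth)) {
    # ground-truth cleft tissue, in the aligned frame
    tissue_all <- pred$aligned_mesh$vertices[labels_truth == "cleft_palate", ,
                                             drop = FALSE]
  } else {
    # estimate the gap tissue: cleft-region scan vertices recessed beyond
    # the healthy palatal course (the unconstrained anchor sphere)
    seg <- segment_scan(reg)
    cand <- reg$scan$vertices[seg == "cleft_palate", , drop = FALSE]
    s0 <- fit_cleft_sphere(reg, safety_distance = 0,
                           tissue = matrix(0, 0, 3))
    depth <- sqrt(colSums((t(cand) - s0$center)^2)) - s0$radius
    tissue_all <- cand[depth > 1, , drop = FALSE]
  }
  sphere <- if (nrow(tissue_all) > 0 || any(cut$labels == "cleft_palate"))
    fit_cleft_sphere(reg, plate$safety_distance, tissue = tissue_all)
  else NULL
  filled <- if (is.null(sphere)) cut$mesh else
    fill_cleft(cut$mesh, cut$labels, sphere,
               relax_iterations = plate$fill_relax_iterations,
               damping = plate$smooth_damping)
  timings["fill"] <- tic() - t0

  t0 <- tic()
  copy1 <- convex_smooth(filled, plate$smooth_iterations_contact,
                         plate$smooth_damping)
  contact <- offset_surface(copy1, plate$contact_offset)
  if (!is.null(sphere) && nrow(tissue_all) > 0) {
    # re-enforce the cleft clearance after smoothing and offsetting:
    # violating fill vertices are projected back onto the sphere
    cl <- which(cut$labels == "cleft_palate")
    for (pass in 1:3) {
      if (!length(cl)) break
      dt <- min_cross_distance(contact$vertices[cl, , drop = FALSE],
                               tissue_all)
      bad <- dt < plate$safety_distance - 1e-9
      if (!any(bad)) break
      idx <- cl[bad]
      P <- contact$vertices[idx, , drop = FALSE]
      dc <- sqrt(rowSums(sweep(P, 2, sphere$center)^2))
      dc[dc < 1e-12] <- 1e-12
      contact$vertices[idx, ] <-
        sweep(sweep(P, 2, sphere$center) * (sphere$radius / dc), 2,
              sphere$center, "+")
    }
  }
  copy2 <- convex_smooth(filled, plate$smooth_iterations_outer,
                         plate$smooth_damping)
  thick <- rep(plate$thickness, nrow(filled$vertices))
  if (!is.null(plate$thickness_scale)) {
    sc <- plate$thickness_scale[as.character(cut$labels)]
    sc[is.na(sc)] <- 1
    thick <- thick * sc
  }
  outer <- offset_surface(copy2, plate$contact_offset + thick)
  # where the strongly smoothed outer copy spans a groove that the
  # contact copy still follows, the sheets could come closer than the
  # plate can be thin: push such outer vertices further out
  Ncon <- vertex_normals(contact)
  sep <- rowSums((outer$vertices - contact$vertices) * Ncon)
  need <- pmax(0, 0.5 * plate$thickness - sep)
  outer$vertices <- outer$vertices + need * Ncon
  solid <- volumize(contact, outer, plate,
                    bulge_scale = as.numeric(cut$labels != "cleft_palate"))
  timings["volumize"] <- tic() - t0

  mask <- which(cut$labels == "alveolar_ridge")
  report <- plate_report(contact, reg$mesh, mask)
  if (nrow(tissue_all) > 0) {
    cleft_idx <- which(cut$labels == "cleft_palate")
    report$clearance <- if (length(cleft_idx))
      min(min_cross_distance(contact$vertices[cleft_idx, , drop = FALSE],
                             tissue_all)) else NA_real_
  }
  quality <- validate_mesh(solid)
  plate_obj <- structure(
    list(mesh = solid, contact = contact, outer = outer,
         labels = cut$labels, params = plate, report = report,
         quality = quality, sphere = sphere),
    class = "palate_plate")
  manifest <- list(
    cleft_type = template$cleft_type,
    n_scan_vertices = nrow(scan$vertices),
    n_template_vertices = nrow(template$mesh$vertices),
    alignment = pred$alignment,
    timings = round(c(timings, total = tic() - t_start), 2),
    warnings = character(0))
  out <- list(plate = plate_obj, registered = reg,
              alignment = pred$alignment, landmarks = pred$landmarks,
              manifest = manifest)
  class(out) <- "plate_fit"
  out
}

#' @export
print.palate_plate <- function(x, ...) {
  cat(sprintf(
    "palate_plate: %d vertices, %d faces, watertight: %s, self-intersections: %d\n",
    nrow(x$mesh$vertices), nrow(x$mesh$faces), x$quality$is_watertight,
    x$quality$self_intersection_count))
  cat(sprintf("  contact distance: %.3f +/- %.3f mm (target %.1f mm)\n",
              x$report$mean, x$report$sd, x$params$contact_offset))
  if (!is.null(x$report$clearance))
    cat(sprintf("  cleft clearance: %.2f mm (safety %.1f mm)\n",
                x$report$clearance, x$params$safety_distance))
  invisible(x)
}

#' @export
print.plate_fit <- function(x, ...) {
  cat("plate_fit\n")
  print(x$plate)
  cat(sprintf("  stage timings (s): %s\n",
              paste(names(x$manifest$timings), x$manifest$timings,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
summary.plate_fit <- function(object, ...) {
  r <- object$plate$report
  out <- data.frame(
    contact_mean_mm = r$mean, contact_sd_mm = r$sd, contact_min_mm = r$min,
    frac_below_neg0.2 = r$frac_below,
    clearance_mm = if (is.null(r$clearance)) NA_real_ else r$clearance,
    watertight = object$plate$quality$is_watertight,
    self_intersections = object$plate$quality$self_intersection_count)
  class(out) <- c("summary.plate_fit", class(out))
  out
}

#' @export
plot.plate_fit <- function(x, slab = 1, ...) {
  # midsagittal cross-section: scan vs plate within |x| < slab (mm)
  sc <- x$registered$scan$vertices
  pl <- x$plate$mesh$vertices
  si <- abs(sc[, 1]) < slab
  pi_ <- abs(pl[, 1]) < slab
  yl <- range(c(sc[si, 3], pl[pi_, 3]))
  graphics::plot(sc[si, 2], sc[si, 3], pch = 16, cex = 0.5, col = "grey40",
       xlab = "anterior-posterior y (mm)", ylab = "z (mm)", ylim = yl,
       main = "midsagittal section: scan (grey) and plate (red)", ...)
  graphics::points(pl[pi_, 2], pl[pi_, 3], pch = 16, cex = 0.5,
                   col = "firebrick")
  invisible(x)
}

#' Run the synthetic fixture suite
#'
#' Generates `n_seeds` synthetic scans of the given cleft type, runs the
#' full pipeline with oracle landmark predictors and default parameters
#' on each, and aggregates the fit metrics.
#'
#' @param n_seeds number of fixture seeds (>= 1).
#' @param cleft_type `"UCLP"` or `"BCLP"`.
#' @param template optional `palate_template` (default generated once).
#' @param seeds optional explicit seed vector.
#' @param params optional base [palate_params()].
#' @param plate a [plate_params()].
#' @return data.frame with one row per seed: landmark error, ridge
#'   registration residual, contact mean/sd, clearance, watertightness,
#'   self-intersections.
#' @export
evaluate_fixture_suite <- function(n_seeds = 10, cleft_type = "UCLP",
                                   template = NULL, seeds = NULL,
                                   params = NULL, plate = plate_params()) {
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  if (is.null(template))
    template <- generate_template(cleft_type, n_samples = 5, seed = 1)
  rows <- lapply(seeds, function(sd) {
    p <- if (is.null(params)) palate_params(cleft_type, seed = sd)
         else { q <- params; q$seed <- as.integer(sd); q }
    scan <- generate_palate(p)
    fit <- compute_plate(scan, template, plate = plate)
    truth_aligned <- apply_transform(scan$landmarks$positions,
                                     fit$alignment)
    lm_err <- mean(sqrt(rowSums(
      (fit$landmarks$positions - truth_aligned)^2)))
    ridge_res <- mean(closest_points(
      fit$registered$mesh$vertices[fit$registered$active1, , drop = FALSE],
      fit$registered$scan)$dist)
    r <- fit$plate$report
    data.frame(seed = sd, landmark_error_mm = lm_err,
               ridge_residual_mm = ridge_res, contact_mean_mm = r$mean,
               contact_sd_mm = r$sd,
               clearance_mm = if (is.null(r$clearance)) NA_real_
                              else r$clearance,
               watertight = fit$plate$quality$is_watertight,
               self_intersections =
                 fit$plate$quality$self_intersection_count)
  })
  do.call(rbind, rows)
}
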