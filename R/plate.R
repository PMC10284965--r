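#' Plate construction parameters
#'
#' Defaults follow the clinical design values: a 0.1 mm contact lift-off
#' so slight scan inaccuracies cannot create pressure points, a 2 mm
#' plate thickness against breakage, and a 2.5 mm safety distance between
#' the filled cleft region and the cleft tissue, leaving room for inward
#' growth.
#'
#' @param contact_offset lift-off of the contact surface (mm).
#' @param thickness plate thickness (mm), must exceed `contact_offset`.
#' @param safety_distance minimum clearance to cleft tissue (mm),
#'   user-adjustable.
#' @param smooth_iterations_contact,smooth_iterations_outer
#'   curvature-selective smoothing passes applied to the contact and
#'   outer copies (light on the contact side to preserve the registered
#'   detail, stronger on the outer side).
#' @param smooth_damping damping of each smoothing step in (0, 1].
#' @param rim_samples half-ellipse samples per boundary pair (>= 1).
#' @param fill_relax_iterations Laplacian relaxation passes after the
#'   spherical projection of the cleft region.
#' @param thickness_scale optional named per-region thickness scale
#'   factors (e.g. a buccal reduction), default 1.
#' @return object of class `plate_params`.
#' @export
plate_params <- function(contact_offset = 0.1, thickness = 2,
                         safety_distance = 2.5,
                         smooth_iterations_contact = 1,
                         smooth_iterations_outer = 5,
                         smooth_damping = 0.5, rim_samples = 8,
                         fill_relax_iterations = 5,
                         thickness_scale = NULL) {
  if (contact_offset <= 0 || thickness <= 0 || safety_distance <= 0)
    stop("all lengths must be positive")
  if (thickness <= contact_offset)
    stop("thickness must exceed contact_offset")
  if (rim_samples < 1) stop("rim_samples must be >= 1")
  structure(list(contact_offset = contact_offset, thickness = thickness,
                 safety_distance = safety_distance,
                 smooth_iterations_contact = smooth_iterations_contact,
                 smooth_iterations_outer = smooth_iterations_outer,
                 smooth_damping = smooth_damping,
                 rim_samples = as.integer(rim_samples),
                 fill_relax_iterations = fill_relax_iterations,
                 thickness_scale = thickness_scale),
            class = "plate_params")
}

#' Cut the plate area out of a registered scan
#'
#' Extracts the submesh of faces whose three vertices belong to the
#' requested regions. The result must form a single connected component
#' (a failure here signals a failed registration).
#'
#' @param registered a `registered_scan`.
#' @param regions labels included in the plate area; by default every
#'   region except `other`.
#' @param check_single_component error when the cut is disconnected (the
#'   default; disable when cutting partial regions for inspection).
#' @return list with `mesh` (open submesh), `labels` (per-vertex labels
#'   of the submesh), `vertex_map` (indices into the registered mesh) and
#'   `n_boundary_loops`.
#' @export
cut_plate_area <- function(registered,
                           regions = c("alveolar_ridge", "cleft_palate",
                                       "bridge", "plate_area"),
                           check_single_component = TRUE) {
  lab <- registered$labels
  keep <- which(lab %in% regions)
  sm <- submesh(registered$mesh, keep)
  comp <- vertex_components(sm$mesh)
  if (check_single_component && max(comp) != 1L)
    stop("plate area is not a single connected component (registration failure?)")
  list(mesh = sm$mesh, labels = lab[sm$vertex_map],
       vertex_map = sm$vertex_map,
       n_boundary_loops = length(boundary_loops(sm$mesh)))
}

#' Fit the cleft-approximation sphere
#'
#' Fits the sphere that connects the left and right alveolar ridges and
#' approximates the course of the cleft palate region: a constrained
#' least-squares fit of `sum_k (||p_k - c|| - r)^2` over the anchor ring
#' (ridge vertices adjacent to the cleft region), subject to every
#' cleft-tissue vertex keeping at least `safety_distance` clearance from
#' the sphere surface (`||q - c|| - r >= safety_distance`). Solved by
#' Nelder-Mead over the centre with the radius eliminated in closed form,
#' from an algebraic sphere-fit initialization.
#'
#' @param registered a `registered_scan`.
#' @param safety_distance clearance to cleft tissue (mm).
#' @param tissue optional matrix of cleft-tissue points; by default the
#'   scan vertices segmented as `cleft_palate` via [segment_scan()].
#' @param max_radius radius cap (mm); by default twice the anchor-ring
#'   span, since a healthy palatal course cannot be flatter than the arch
#'   scale (a fixed 200 mm cap guards truly degenerate configurations).
#' @return object of class `cleft_sphere`: list with `center`, `radius`,
#'   `anchors`, `constraint_active`.
#' @export
fit_cleft_sphere <- function(registered, safety_distance = 2.5,
                             tissue = NULL, max_radius = NULL) {
  lab <- registered$labels
  V <- registered$mesh$vertices
  cleft <- which(lab == "cleft_palate")
  if (!length(cleft)) stop("cleft_palate region is empty")
  adj <- vertex_adjacency(registered$mesh)
  # margin ring: every vertex bordering the cleft region, i.e. the ridge
  # arcs on both sides plus the surrounding palate, so the fill comes out
  # tangent-continuous with its surroundings
  other <- which(!(lab == "cleft_palate"))
  anchors_idx <- other[vapply(adj[other], function(nb)
    any(nb %in% cleft), TRUE)]
  if (length(anchors_idx) < 4L)
    stop("too few anchors adjacent to the cleft region")
  anchors <- V[anchors_idx, , drop = FALSE]
  if (is.null(tissue)) {
    seg <- segment_scan(registered)
    tissue <- registered$scan$vertices[seg == "cleft_palate", , drop = FALSE]
  }
  if (is.null(max_radius)) {
    span <- max(dist(anchors))
    max_radius <- min(200, 2 * span)
  }
  # the sphere centre must lie on the mouth side of the palate; the mean
  # vertex normal (oriented into the mouth) provides the hint
  down <- colMeans(vertex_normals(registered$mesh))
  down <- down / sqrt(sum(down^2))
  fit_sphere_constrained(anchors, tissue, safety_distance, max_radius,
                         anchors_idx, down = down)
}

#' Constrained least-squares sphere fit
#'
#' Fits `sum_k (||p_k - c|| - r)^2` over `anchors`, optionally subject to
#' `||q - c|| - r >= safety_distance` for every row `q` of `tissue`
#' (points kept clear outside the sphere). Used by [fit_cleft_sphere()];
#' exposed for direct fits on explicit point sets.
#'
#' @param anchors n x 3 matrix of points the sphere should pass through.
#' @param tissue optional m x 3 matrix of clearance points.
#' @param safety_distance clearance (mm); 0 disables the constraint.
#' @param max_radius radius cap for degenerate (flat) configurations.
#' @param anchors_idx optional bookkeeping indices stored on the result.
#' @return a `cleft_sphere` object.
#' @export
fit_sphere <- function(anchors, tissue = NULL, safety_distance = 0,
                       max_radius = 200, anchors_idx = NULL) {
  fit_sphere_constrained(anchors, tissue, safety_distance, max_radius,
                         anchors_idx)
}

# constrained sphere fit on explicit point sets; `down` is an optional
# unit hint for the half space the centre must lie in (the mouth side)
fit_sphere_constrained <- function(anchors, tissue, safety_distance,
                                   max_radius = 200, anchors_idx = NULL,
                                   down = NULL) {
  centroid <- colMeans(anchors)
  span <- max(stats::dist(anchors))
  # algebraic initialization: ||p||^2 = 2 c . p + (r^2 - ||c||^2)
  A <- cbind(2 * anchors, 1)
  b <- rowSums(anchors^2)
  beta <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                   error = function(e) NULL)
  c0 <- if (is.null(beta)) centroid else as.numeric(beta[1:3])
  r0sq <- if (is.null(beta)) 0 else beta[4] + sum(c0^2)
  if (!is.finite(r0sq) || r0sq <= 0 || sqrt(r0sq) > max_radius) {
    warning("near-degenerate anchor configuration; capping sphere radius")
    c0 <- centroid
  }
  if (!is.null(down) && sum((c0 - centroid) * down) < 0) {
    # algebraic centre on the tissue side: reflect it to the mouth side
    c0 <- c0 - 2 * sum((c0 - centroid) * down) * down
  }
  has_tissue <- !is.null(tissue) && nrow(tissue) > 0 && safety_distance > 0
  radius_for <- function(cen) {
    d <- sqrt(colSums((t(anchors) - cen)^2))
    r <- min(mean(d), max_radius)
    if (has_tissue) {
      rmax <- min(sqrt(colSums((t(tissue) - cen)^2))) - safety_distance
      r <- min(r, rmax)
    }
    list(r = r, d = d)
  }
  objective <- function(cen) {
    rf <- radius_for(cen)
    if (rf$r <= 0) return(1e9 + abs(rf$r) * 1e6)
    sum((rf$d - rf$r)^2)
  }
  starts <- list(c0)
  if (!is.null(down)) {
    starts <- c(starts, list(centroid + 0.5 * span * down,
                             centroid + 1.0 * span * down))
  }
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  cen <- best$par
  rf <- radius_for(cen)
  if (rf$r <= 0)
    stop(sprintf(
      "infeasible safety constraint: violated by %.2f mm", -rf$r))
  active <- FALSE
  if (has_tissue) {
    slack <- min(sqrt(colSums((t(tissue) - cen)^2))) -
      safety_distance - rf$r
    active <- slack < 1e-4
  }
  structure(list(center = as.numeric(cen), radius = rf$r,
                 anchors = anchors, anchor_idx = anchors_idx,
                 constraint_active = active,
                 safety_distance = if (has_tissue) safety_distance else 0,
                 tissue = if (has_tissue) tissue else NULL),
            class = "cleft_sphere")
}

#' @export
print.cleft_sphere <- function(x, ...) {
  cat(sprintf(
    "cleft_sphere: centre (%.1f, %.1f, %.1f) mm, radius %.2f mm, constraint %s\n",
    x$center[1], x$center[2], x$center[3], x$radius,
    if (x$constraint_active) "active" else "inactive"))
  invisible(x)
}

#' Fill the cleft region around the fitted sphere
#'
#' Imitates a healthy palate shape: cleft-region vertices are blended
#' toward their radial projection onto the sphere (the blend weight grows
#' with graph distance from the region boundary, giving a smooth
#' transition into the surrounding plate surface), relaxed by a few
#' Laplacian passes with the region-boundary vertices held fixed, and
#' finally any vertex closer than the safety distance to the cleft
#' tissue is snapped onto the sphere, which restores the clearance
#' (tissue lies at least `safety_distance` outside the sphere). Vertices
#' outside the cleft region are untouched.
#'
#' @param surface an open [tri_mesh()] (the cut plate area).
#' @param labels per-vertex labels of `surface`.
#' @param sphere a `cleft_sphere`; its `tissue`/`safety_distance` fields
#'   (set by [fit_cleft_sphere()]) drive the clearance enforcement.
#' @param relax_iterations Laplacian relaxation passes (default 5).
#' @param damping relaxation damping.
#' @param blend_hops graph distance from the region boundary at which the
#'   spherical projection reaches full weight.
#' @return the surface with the filled cleft region.
#' @export
fill_cleft <- function(surface, labels, sphere, relax_iterations = 5,
                       damping = 0.5, blend_hops = 4) {
  V <- surface$vertices
  cleft <- which(labels == "cleft_palate")
  if (!length(cleft)) return(surface)
  cen <- sphere$center
  r <- sphere$radius
  proj <- function(P) {
    d <- sqrt(rowSums(sweep(P, 2, cen)^2))
    d[d < 1e-12] <- 1e-12
    sweep(sweep(P, 2, cen) * (r / d), 2, cen, "+")
  }
  adj <- vertex_adjacency(surface)
  # BFS hop distance from the region boundary (non-cleft neighbours)
  incleft <- logical(nrow(V))
  incleft[cleft] <- TRUE
  hops <- rep(Inf, nrow(V))
  frontier <- cleft[vapply(adj[cleft], function(nb) any(!incleft[nb]), TRUE)]
  hops[frontier] <- 1
  depth <- 1
  while (length(frontier) && depth < blend_hops + 1L) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[incleft[nxt] & hops[nxt] > depth + 1]
    hops[nxt] <- depth + 1
    frontier <- nxt
    depth <- depth + 1
  }
  w <- if (blend_hops > 0) pmin(1, (hops[cleft] - 1) / blend_hops)
       else rep(1, length(cleft))
  w[!is.finite(w)] <- 1
  # vertices beyond the sphere lie on the tissue side of the healthy
  # course (recessed gap walls): those are always fully projected
  dc <- sqrt(rowSums(sweep(V[cleft, , drop = FALSE], 2, cen)^2))
  w[dc > r] <- 1
  # genuinely recessed gap walls (well beyond the healthy course); the
  # border treatment below applies only to those
  recessed <- logical(nrow(V))
  recessed[cleft[dc > r + 1]] <- TRUE
  P <- proj(V[cleft, , drop = FALSE])
  V[cleft, ] <- (1 - w) * V[cleft, , drop = FALSE] + w * P
  for (it in seq_len(relax_iterations)) {
    upd <- t(vapply(cleft, function(i) colMeans(V[adj[[i]], , drop = FALSE]),
                    numeric(3)))
    V[cleft, ] <- V[cleft, , drop = FALSE] +
      damping * (upd - V[cleft, , drop = FALSE])
  }
  # where the gap crosses the plate border, the projected border dents
  # inward; smooth that border segment along the boundary curve so the
  # plate outline spans the gap mouth cleanly
  loops <- boundary_loops(surface)
  for (loop in loops) {
    nb <- length(loop)
    mv <- which(incleft[loop] & recessed[loop])
    if (!length(mv) || nb < 3) next
    for (pass in 1:15) {
      upd <- (V[loop[c(nb, 1:(nb - 1))], , drop = FALSE] +
              V[loop[c(2:nb, 1)], , drop = FALSE]) / 2
      V[loop[mv], ] <- V[loop[mv], , drop = FALSE] +
        damping * (upd[mv, , drop = FALSE] - V[loop[mv], , drop = FALSE])
    }
  }
  # clearance enforcement: violating vertices are snapped to the sphere
  if (!is.null(sphere$tissue) && sphere$safety_distance > 0) {
    for (pass in 1:3) {
      dt <- min_cross_distance(V[cleft, , drop = FALSE], sphere$tissue)
      bad <- dt < sphere$safety_distance - 1e-9
      if (!any(bad)) break
      idx <- cleft[bad]
      V[idx, ] <- proj(V[idx, , drop = FALSE])
    }
  }
  surface$vertices <- V
  surface
}

#' Curvature-selective (convex) smoothing
#'
#' One smoothing pass moves exactly the vertices whose uniform-Laplacian
#' (discrete mean-curvature) vector points along the offset direction,
#' i.e. the vertices around which a normal offset would locally
#' self-intersect; they are displaced by `damping` times the Laplacian.
#' Flat and oppositely curved (dimple) vertices are untouched, which
#' preserves the high-frequency detail of the contact region.
#'
#' @param surface an open [tri_mesh()].
#' @param iterations number of passes (>= 0).
#' @param damping step size in (0, 1].
#' @param direction optional n x 3 offset directions (default the vertex
#'   normals, recomputed each pass).
#' @return the smoothed surface.
#' @export
convex_smooth <- function(surface, iterations = 1, damping = 0.5,
                          direction = NULL) {
  if (iterations < 1) return(surface)
  adj <- vertex_adjacency(surface)
  bv <- boundary_vertices(surface)
  if (length(bv)) {
    # boundary vertices are smoothed along the boundary curve only
    be <- boundary_edges(surface)
    badj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
    for (i in bv) adj[[i]] <- as.integer(badj[[as.character(i)]])
  }
  for (it in seq_len(iterations)) {
    V <- surface$vertices
    N <- if (is.null(direction)) vertex_normals(surface) else direction
    lap <- t(vapply(seq_len(nrow(V)), function(i)
      colMeans(V[adj[[i]], , drop = FALSE]) - V[i, ], numeric(3)))
    comp <- rowSums(lap * N)
    move <- which(comp > 1e-9)
    V[move, ] <- V[move, , drop = FALSE] + damping * lap[move, , drop = FALSE]
    # boundary vertices move along their normals only, so copies that are
    # smoothed with different intensities keep corresponding borders
    mb <- intersect(move, bv)
    if (length(mb)) {
      V[mb, ] <- surface$vertices[mb, , drop = FALSE] +
        damping * comp[mb] * N[mb, , drop = FALSE]
    }
    surface$vertices <- V
  }
  surface
}

#' Offset a surface along its vertex normals
#'
#' `v' = v + distance * n(v)` with area-weighted vertex normals; the
#' topology is unchanged.
#'
#' @param surface a [tri_mesh()].
#' @param distance offset (mm); positive moves along the normals.
#' @param normals optional fixed normals (default recomputed).
#' @return the offset surface.
#' @export
offset_surface <- function(surface, distance, normals = NULL) {
  if (is.null(normals)) normals <- vertex_normals(surface)
  surface$vertices <- surface$vertices + distance * normals
  surface$normals <- NULL
  surface
}

#' Stitch contact and outer surfaces into a watertight plate solid
#'
#' The two copies must share topology and a single boundary loop; each
#' pair of corresponding boundary vertices is connected by a sampled
#' half-ellipse whose minor axis is the pair's separation and whose major
#' semi-axis bulges outward by `thickness / 2`, giving a smooth border
#' transition. The assembled mesh is consistently oriented outward and
#' must validate watertight and self-intersection free.
#'
#' @param contact,outer [tri_mesh()] copies with identical topology.
#' @param params a [plate_params()].
#' @param check validate the result (default `TRUE`).
#' @param bulge_scale optional per-vertex scale in `[0, 1]` for the rim
#'   bulge (smoothed along the boundary loop); the pipeline uses it to
#'   flatten the rim where the border crosses the filled cleft region.
#' @return a watertight [tri_mesh()] solid.
#' @export
volumize <- function(contact, outer, params = plate_params(), check = TRUE,
                     bulge_scale = NULL) {
  if (!identical(dim(contact$vertices), dim(outer$vertices)) ||
      !identical(contact$faces, outer$faces))
    stop("contact and outer surfaces must share topology")
  loops <- boundary_loops(contact)
  if (length(loops) != 1L)
    stop("plate surface must have exactly one boundary loop")
  loop <- loops[[1]]
  nb <- length(loop)
  k <- params$rim_samples
  adj <- vertex_adjacency(contact)
  nV <- nrow(contact$vertices)

  Vc <- contact$vertices
  Vo <- outer$vertices
  bulge <- params$thickness / 2
  ringV <- vector("list", k - 1L)
  if (k > 1L) {
    # outward in-plane directions at the boundary
    Ow <- t(vapply(loop, function(i) {
      o <- Vc[i, ] - colMeans(Vc[adj[[i]], , drop = FALSE])
      d <- Vo[i, ] - Vc[i, ]
      dl <- sqrt(sum(d^2))
      if (dl > 1e-12) {
        dh <- d / dl
        o <- o - sum(o * dh) * dh
      }
      ol <- sqrt(sum(o^2))
      if (ol < 1e-12) o <- c(0, 0, 0) else o <- o / ol
      o
    }, numeric(3)))
    # smooth the outward directions along the loop so adjacent
    # half-ellipses cannot cross at boundary corners
    for (s in 1:3) {
      Ow <- (Ow + Ow[c(nb, 1:(nb - 1)), ] + Ow[c(2:nb, 1), ]) / 3
      len <- sqrt(rowSums(Ow^2))
      len[len < 1e-12] <- 1
      Ow <- Ow / len
    }
    sc <- rep(1, nb)
    if (!is.null(bulge_scale)) {
      sc <- pmin(1, pmax(0, bulge_scale[loop]))
      for (s in 1:3) sc <- (sc + sc[c(nb, 1:(nb - 1))] + sc[c(2:nb, 1)]) / 3
    }
    for (j in seq_len(k - 1L)) {
      th <- pi * j / k
      mid <- (Vc[loop, , drop = FALSE] + Vo[loop, , drop = FALSE]) / 2
      d <- Vo[loop, , drop = FALSE] - Vc[loop, , drop = FALSE]
      ringV[[j]] <- mid - cos(th) / 2 * d + (bulge * sc) * sin(th) * Ow
    }
  }
  V <- rbind(Vc, Vo, do.call(rbind, ringV))
  ring_ids <- function(j) {
    if (j == 0L) loop
    else if (j == k) loop + nV
    else 2L * nV + (j - 1L) * nb + seq_len(nb)
  }
  F <- rbind(contact$faces, outer$faces[, c(1, 3, 2)] + nV)
  for (j in seq_len(k)) {
    a <- ring_ids(j - 1L)
    b <- ring_ids(j)
    nxt <- c(2:nb, 1L)
    F <- rbind(F,
               cbind(a, a[nxt], b[nxt]),
               cbind(a, b[nxt], b))
  }
  solid <- orient_mesh(tri_mesh(V, F))
  # local fold repair: any residual self-intersections (tight valleys
  # narrower than the offset) are relaxed away on the outer/rim side;
  # contact-sheet vertices are never moved, preserving the fit
  solid <- relax_fold_regions(solid, protect = seq_len(nV))
  if (check) {
    rep <- validate_mesh(solid)
    if (!rep$is_watertight)
      stop("volumization produced a non-watertight mesh")
    if (rep$self_intersection_count > 0)
      stop(sprintf(
        "volumization left %d self-intersections after repair",
        rep$self_intersection_count))
  }
  solid
}

# iterative local Laplacian relaxation of self-intersecting regions;
# a relaxation round is only accepted when it reduces the intersection
# count, so the repair is monotone and cannot diverge
relax_fold_regions <- function(mesh, protect = integer(0), rounds = 40,
                               damping = 0.5) {
  adj <- vertex_adjacency(mesh)
  pr <- cpp_self_intersection_pairs(mesh$vertices, mesh$faces)
  n_cur <- nrow(pr)
  d <- damping
  ring <- 1L
  for (r in seq_len(rounds)) {
    if (n_cur == 0L) break
    ids <- unique(as.vector(mesh$faces[unique(as.vector(pr)), ]))
    for (k in seq_len(ring)) ids <- unique(c(ids, unlist(adj[ids])))
    ids <- setdiff(ids, protect)
    if (!length(ids)) break
    prop <- mesh
    V <- prop$vertices
    for (pass in seq_len(ring)) {
      upd <- t(vapply(ids, function(i) colMeans(V[adj[[i]], , drop = FALSE]),
                      numeric(3)))
      V[ids, ] <- V[ids, , drop = FALSE] + d * (upd - V[ids, , drop = FALSE])
    }
    prop$vertices <- V
    pr_new <- cpp_self_intersection_pairs(prop$vertices, prop$faces)
    if (nrow(pr_new) < n_cur) {
      mesh <- prop
      pr <- pr_new
      n_cur <- nrow(pr_new)
      d <- damping
      ring <- 1L
    } else if (d >= 0.05) {
      d <- d / 2
    } else if (ring < 4L) {
      # stuck: escalate to a wider neighbourhood and stronger smoothing
      ring <- ring + 1L
      d <- damping
    } else {
      break
    }
  }
  mesh
}

#' Signed-distance fit report of a plate contact surface
#'
#' Mean and spread of the signed point-to-plane distance from the
#' contact-surface vertices in the contact (alveolar-ridge) region to the
#' reference surface, plus pressure-point diagnostics.
#'
#' @param contact the plate contact surface ([tri_mesh()]).
#' @param reference the registered scan surface.
#' @param mask integer vertex indices of the contact region.
#' @return list with `mean`, `sd`, `min`, `max` (mm), `n` and
#'   `frac_below` (fraction of distances below -0.2 mm).
#' @export
plate_report <- function(contact, reference, mask) {
  if (missing(mask) || length(mask) == 0L) stop("empty contact mask")
  sdf <- signed_point_to_plane_distance(contact, reference, mask)
  list(mean = sdf$mean, sd = sdf$sd, min = min(sdf$distances),
       max = max(sdf$distances), n = length(sdf$distances),
       frac_below = mean(sdf$distances < -0.2))
}
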