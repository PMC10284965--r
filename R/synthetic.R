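#' Parameters of the synthetic neonatal palate generator
#'
#' The generator emulates an intraoral surface scan of a neonatal maxilla:
#' a smooth arched palatal vault bounded by an alveolar ridge, with zero,
#' one or two cleft gaps cut through ridge and palate. Default dimensions
#' are typical neonatal values (arch about 34 x 28 mm, vault depth 7 mm).
#' The mesh is a fixed fan-shaped parametric grid (angle along the arch,
#' radius from the posterior midline), so all meshes generated for one
#' cleft type and resolution share vertex topology.
#'
#' The canonical frame is: occlusal plane approximately xy, anterior +y,
#' superior (into the vault) +z. Faces are wound so vertex normals point
#' away from the tissue, into the mouth.
#'
#' @param cleft_type `"UCLP"` (one gap), `"BCLP"` (two gaps isolating a
#'   premaxilla) or `"ISOLATED_HEALTHY_RIDGE"` (no gap; the geometry used
#'   for the bridging template).
#' @param arch_width,arch_length outer arch half-axes x 2 (mm).
#' @param vault_depth height of the palatal vault above the ridge base (mm).
#' @param ridge_height,ridge_width alveolar ridge drop and radial width (mm).
#' @param cleft_width gap width measured along the ridge (mm).
#' @param cleft_position arc-length fraction in (0, 1) of the cleft centre
#'   (UCLP) or of the premaxilla centre (BCLP); 0 is the left posterior
#'   ridge end, 0.5 the anterior midline.
#' @param cleft_depth recess of the cleft tissue above the local surface (mm).
#' @param premaxilla_width width of the premaxilla between the BCLP gaps (mm).
#' @param shape_variation amplitude of the random smooth shape variation (mm).
#' @param noise_sd standard deviation of per-vertex surface noise (mm).
#' @param rigid_pose optional [rigid_transform()] applied to the result.
#' @param n_arc,n_rad grid resolution along the arch and radially.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return object of class `palate_params`.
#' @export
palate_params <- function(cleft_type = c("UCLP", "BCLP", "ISOLATED_HEALTHY_RIDGE"),
                          arch_width = 34, arch_length = 28, vault_depth = 7,
                          ridge_height = 3.5, ridge_width = 5,
                          cleft_width = NULL, cleft_position = NULL,
                          cleft_depth = 8, premaxilla_width = 10,
                          shape_variation = 0.8, noise_sd = 0.05,
                          rigid_pose = NULL, n_arc = 48, n_rad = 18,
                          seed = 1) {
  cleft_type <- match.arg(cleft_type)
  if (is.null(cleft_width))
    cleft_width <- switch(cleft_type, UCLP = 8, BCLP = 6,
                          ISOLATED_HEALTHY_RIDGE = 8)
  if (is.null(cleft_position))
    cleft_position <- switch(cleft_type, UCLP = 0.35, BCLP = 0.5,
                             ISOLATED_HEALTHY_RIDGE = 0.35)
  lens <- c(arch_width = arch_width, arch_length = arch_length,
            vault_depth = vault_depth, ridge_height = ridge_height,
            ridge_width = ridge_width, cleft_width = cleft_width,
            cleft_depth = cleft_depth, premaxilla_width = premaxilla_width)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (cleft_width >= arch_width) stop("cleft_width must be < arch_width")
  if (cleft_position <= 0 || cleft_position >= 1)
    stop("cleft_position must lie in (0, 1)")
  if (shape_variation < 0 || noise_sd < 0)
    stop("shape_variation and noise_sd must be non-negative")
  if (!is.null(rigid_pose) && !inherits(rigid_pose, "rigid_transform"))
    stop("rigid_pose must be a rigid_transform")
  if (n_arc < 12 || n_rad < 6) stop("grid resolution too coarse")
  out <- list(cleft_type = cleft_type, arch_width = arch_width,
              arch_length = arch_length, vault_depth = vault_depth,
              ridge_height = ridge_height, ridge_width = ridge_width,
              cleft_width = cleft_width, cleft_position = cleft_position,
              cleft_depth = cleft_depth, premaxilla_width = premaxilla_width,
              shape_variation = shape_variation, noise_sd = noise_sd,
              rigid_pose = rigid_pose, n_arc = as.integer(n_arc),
              n_rad = as.integer(n_rad), seed = as.integer(seed))
  class(out) <- "palate_params"
  out
}

#' @export
print.palate_params <- function(x, ...) {
  cat(sprintf(
    "palate_params: %s, arch %g x %g mm, vault %g mm, ridge %g/%g mm,\n  cleft %g mm at %.2f, grid %d x %d, seed %d\n",
    x$cleft_type, x$arch_width, x$arch_length, x$vault_depth,
    x$ridge_height, x$ridge_width, x$cleft_width, x$cleft_position,
    x$n_arc, x$n_rad, x$seed))
  invisible(x)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# --- internal parametric model ----------------------------------------

# radial physical scale of the arch at angle phi
arch_radius <- function(p, phi) {
  sqrt((p$arch_width / 2 * cos(phi))^2 + (p$arch_length * sin(phi))^2)
}

# cleft sectors: matrix with columns phi_c (centre angle) and alpha
# (angular half width); physically placed so the gap chord matches
# cleft_width at the ridge crest
cleft_sectors <- function(p) {
  crest_radius <- function(phi) {
    R <- arch_radius(p, phi)
    R * (1 - 0.5 * p$ridge_width / R)
  }
  if (p$cleft_type == "UCLP") {
    phi_c <- pi * (1 - p$cleft_position)
    alpha <- p$cleft_width / (2 * crest_radius(phi_c))
    cbind(phi_c = phi_c, alpha = alpha)
  } else if (p$cleft_type == "BCLP") {
    phi_p <- pi * (1 - p$cleft_position)
    Rc <- crest_radius(phi_p)
    dphi <- (p$premaxilla_width / 2 + p$cleft_width / 2) / Rc
    phis <- c(phi_p + dphi, phi_p - dphi)
    cbind(phi_c = phis,
          alpha = p$cleft_width / (2 * vapply(phis, crest_radius, 0)))
  } else {
    cbind(phi_c = numeric(0), alpha = numeric(0))
  }
}

# per-point cleft displacement factor in [0, 1]; steep-walled plateau
# profile so the gap has a crisp margin
cleft_factor <- function(p, phi, rho, healthy = FALSE) {
  f <- numeric(length(phi))
  if (healthy) return(f)
  sec <- cleft_sectors(p)
  if (nrow(sec) == 0) return(f)
  R <- arch_radius(p, phi)
  rho_r <- 1 - p$ridge_width / R
  # radial onset: the gap cuts through the ridge and the adjacent palate
  r1 <- rho_r - 0.45
  r0 <- rho_r - 0.2
  u <- pmin(1, pmax(0, (rho - r1) / (r0 - r1)))
  h <- u * u * (3 - 2 * u)
  x <- rho * (p$arch_width / 2) * cos(phi)
  y <- rho * p$arch_length * sin(phi)
  for (k in seq_len(nrow(sec))) {
    # perpendicular distance (mm) to the cleft centre ray in the
    # occlusal plane: the gap is a constant-width channel, steep walls
    ux <- p$arch_width / 2 * cos(sec[k, "phi_c"])
    uy <- p$arch_length * sin(sec[k, "phi_c"])
    un <- sqrt(ux^2 + uy^2)
    d <- abs(x * uy - y * ux) / un
    ahead <- (x * ux + y * uy) > 0  # only the half plane of the ray
    t <- d / (p$cleft_width / 2)
    g <- ifelse(t >= 1 | !ahead, 0, pmin(1, 3 * (1 - t^2)))
    f <- pmax(f, g * h)
  }
  f
}

# base surface height (mm) before cleft displacement
base_height <- function(p, phi, rho) {
  R <- arch_radius(p, phi)
  w <- p$ridge_width / R
  rho_r <- 1 - w
  z <- numeric(length(phi))
  inner <- rho <= rho_r
  z[inner] <- p$vault_depth * (1 - (rho[inner] / rho_r[inner])^2)
  s <- (rho - rho_r) / w
  z[!inner] <- -p$ridge_height * sin(pi * pmin(1, s[!inner]))
  z
}

# full base position (canonical frame, no variation/noise/pose)
palate_points <- function(p, phi, rho, healthy = FALSE) {
  x <- rho * (p$arch_width / 2) * cos(phi)
  y <- rho * p$arch_length * sin(phi)
  z <- base_height(p, phi, rho) +
    p$cleft_depth * cleft_factor(p, phi, rho, healthy = healthy)
  cbind(x, y, z)
}

# smooth low-frequency displacement field: sum of 3 random cosine modes,
# rescaled so the maximum displacement over `at` equals `magnitude`
random_smooth_field <- function(magnitude, at) {
  m <- 3L
  dirs <- matrix(stats::rnorm(3 * m), m, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amps <- matrix(stats::rnorm(3 * m), m, 3)
  amps <- amps / sqrt(rowSums(amps^2))
  lambda <- stats::runif(m, 25, 45)
  phase <- stats::runif(m, 0, 2 * pi)
  field <- function(pts) {
    pts <- matrix(as.numeric(pts), ncol = 3)
    d <- matrix(0, nrow(pts), 3)
    for (k in seq_len(m)) {
      arg <- 2 * pi * (pts %*% dirs[k, ]) / lambda[k] + phase[k]
      d <- d + outer(as.vector(cos(arg)), amps[k, ])
    }
    d
  }
  if (magnitude <= 0) return(function(pts) 0 * matrix(as.numeric(pts), ncol = 3))
  mx <- max(sqrt(rowSums(field(at)^2)))
  if (mx < 1e-12) return(function(pts) 0 * matrix(as.numeric(pts), ncol = 3))
  sc <- magnitude / mx
  function(pts) sc * field(pts)
}

# fan grid over the half disk; returns phi, rho per vertex and faces
palate_grid <- function(n_arc, n_rad) {
  phi <- c(pi / 2, rep(pi * (seq_len(n_arc) - 1) / (n_arc - 1), n_rad))
  rho <- c(0, rep(seq_len(n_rad) / n_rad, each = n_arc))
  idx <- function(i, j) 1L + (i - 1L) * n_arc + j
  faces <- matrix(0L, (n_arc - 1L) * (2L * n_rad - 1L), 3L)
  r <- 1L
  for (j in seq_len(n_arc - 1L)) {       # centre fan
    faces[r, ] <- c(1L, idx(1L, j), idx(1L, j + 1L))
    r <- r + 1L
  }
  for (i in seq_len(n_rad - 1L)) {
    for (j in seq_len(n_arc - 1L)) {
      faces[r, ] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
      faces[r + 1L, ] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      r <- r + 2L
    }
  }
  list(phi = phi, rho = rho, faces = faces)
}

#' Region label names
#' @return character vector of the five region labels.
#' @export
palate_region_names <- function() {
  c("alveolar_ridge", "cleft_palate", "bridge", "plate_area", "other")
}

# angular half width of the central fill wedge used on templates
fill_wedge_halfwidth <- function(p) {
  sec <- cleft_sectors(p)
  if (nrow(sec) == 0) {
    a <- p$cleft_width / (2 * arch_radius(p, pi / 2))
    return(a + 0.15)
  }
  max(abs(sec[, "phi_c"] - pi / 2) + sec[, "alpha"]) + 0.15
}

# per-vertex labels; kind "scan" marks the recessed gap tissue as
# cleft_palate, kind "template" marks the central fill wedge (and, for
# UCLP, the bridge sector of the ridge)
palate_labels <- function(p, phi, rho, f, kind = c("scan", "template"),
                          healthy = FALSE) {
  kind <- match.arg(kind)
  R <- arch_radius(p, phi)
  rho_r <- 1 - p$ridge_width / R
  y_base <- rho * p$arch_length * sin(phi)
  y_cut <- 0.15 * p$arch_length
  ridge <- rho > rho_r
  lab <- rep("plate_area", length(phi))
  lab[!ridge & y_base < y_cut] <- "other"
  lab[ridge] <- "alveolar_ridge"
  if (kind == "scan") {
    lab[f > 0.3] <- "cleft_palate"
  } else {
    wedge <- abs(phi - pi / 2) <= fill_wedge_halfwidth(p)
    # also cover the cleft channel(s) plus a 3 mm margin, so the fill
    # absorbs the registered gap walls entirely
    sec <- cleft_sectors(if (p$cleft_type == "ISOLATED_HEALTHY_RIDGE") {
      q <- p
      q$cleft_type <- "UCLP"
      q
    } else p)
    x <- rho * (p$arch_width / 2) * cos(phi)
    y <- rho * p$arch_length * sin(phi)
    near_channel <- rep(FALSE, length(phi))
    for (k in seq_len(nrow(sec))) {
      ux <- p$arch_width / 2 * cos(sec[k, "phi_c"])
      uy <- p$arch_length * sin(sec[k, "phi_c"])
      un <- sqrt(ux^2 + uy^2)
      d <- abs(x * uy - y * ux) / un
      ahead <- (x * ux + y * uy) > 0
      near_channel <- near_channel |
        (ahead & d < p$cleft_width / 2 + 3)
    }
    lab[!ridge & (wedge | near_channel) & y_base >= y_cut] <- "cleft_palate"
    # absorb even slightly recessed gap shoulders into the fill region:
    # leftover grooves narrower than the plate thickness are unprintable
    lab[f > 0.05] <- "cleft_palate"
    if (p$cleft_type == "UCLP" && healthy) {
      sec <- cleft_sectors(p)
      bridge <- ridge & abs(phi - sec[1, "phi_c"]) <= sec[1, "alpha"]
      lab[bridge] <- "bridge"
    }
  }
  factor(lab, levels = palate_region_names())
}

# parametric (phi, rho) positions of the 10 landmarks
landmark_parameters <- function(p) {
  R <- function(phi) arch_radius(p, phi)
  rho_crest <- function(phi) 1 - 0.5 * p$ridge_width / R(phi)
  sec <- cleft_sectors(p)
  if (nrow(sec) == 0) {
    # healthy ridge: margins where the UCLP gap would sit
    q <- p
    q$cleft_type <- "UCLP"
    sec <- cleft_sectors(q)
  }
  if (nrow(sec) == 1L) {
    mL <- sec[1, "phi_c"] + sec[1, "alpha"]
    mR <- sec[1, "phi_c"] - sec[1, "alpha"]
  } else {
    # BCLP: premaxilla-adjacent margins
    mL <- max(sec[, "phi_c"]) - sec[which.max(sec[, "phi_c"]), "alpha"]
    mR <- min(sec[, "phi_c"]) + sec[which.min(sec[, "phi_c"]), "alpha"]
  }
  wd <- fill_wedge_halfwidth(p)
  phis <- c(pi * 0.96, pi * 0.04, pi * 0.72, pi * 0.28, mL, mR,
            pi / 2, pi / 2, pi / 2 + 0.6 * wd, pi / 2 - 0.6 * wd)
  rhos <- c(rho_crest(pi * 0.96), rho_crest(pi * 0.04),
            rho_crest(pi * 0.72), rho_crest(pi * 0.28),
            rho_crest(mL), rho_crest(mR),
            rho_crest(pi / 2), 0.3, 0.6, 0.6)
  cbind(phi = phis, rho = rhos)
}

#' Generate a synthetic cleft palate scan
#'
#' Builds a palate surface on a fixed parametric grid, adds a random
#' smooth shape variation and per-vertex surface noise, optionally poses
#' it rigidly, and returns the mesh together with ground-truth landmarks
#' and per-vertex region labels. Deterministic given `params$seed`.
#'
#' @param params a [palate_params()] object.
#' @return object of class `palate_scan`: list with `mesh`
#'   (a [tri_mesh()]), `landmarks` (a [landmark_set()]), `labels`
#'   (factor over [palate_region_names()]), and `params`.
#' @examples
#' scan <- generate_palate(palate_params("UCLP", seed = 7))
#' scan
#' @export
generate_palate <- function(params) {
  stopifnot(inherits(params, "palate_params"))
  generate_palate_core(params, healthy = FALSE, label_kind = "scan")
}

generate_palate_core <- function(params, healthy, label_kind) {
  p <- params
  g <- palate_grid(p$n_arc, p$n_rad)
  V <- palate_points(p, g$phi, g$rho, healthy = healthy)
  f <- cleft_factor(p, g$phi, g$rho, healthy = healthy)
  labels <- palate_labels(p, g$phi, g$rho, f, kind = label_kind,
                          healthy = healthy)
  lp <- landmark_parameters(p)
  L <- palate_points(p, lp[, "phi"], lp[, "rho"], healthy = healthy)
  rownames(L) <- palate_landmark_names()

  with_seed(p$seed, {
    field <- random_smooth_field(p$shape_variation, V)
    V <- V + field(V)
    L <- L + field(L)
    mesh <- tri_mesh(V, g$faces)
    mesh <- orient_palate(mesh)
    if (p$noise_sd > 0) {
      N <- vertex_normals(mesh)
      mesh$vertices <- mesh$vertices + p$noise_sd * stats::rnorm(nrow(V)) * N
    }
  })
  if (!is.null(p$rigid_pose)) {
    mesh <- apply_transform(mesh, p$rigid_pose)
    L <- apply_transform(L, p$rigid_pose)
  }
  out <- list(mesh = mesh, landmarks = landmark_set(L), labels = labels,
              params = p)
  class(out) <- "palate_scan"
  out
}

# wind faces so vertex normals point into the mouth (-z in canonical frame)
orient_palate <- function(mesh) {
  fn <- face_normals(mesh)
  if (sum(fn$normals[, 3] * fn$areas) > 0) mesh <- flip_mesh(mesh)
  mesh
}

#' @export
print.palate_scan <- function(x, ...) {
  cat(sprintf("palate_scan (%s): %d vertices, %d faces\n",
              x$params$cleft_type, nrow(x$mesh$vertices), nrow(x$mesh$faces)))
  print(table(x$labels))
  invisible(x)
}

#' Average meshes with shared topology into a labeled template
#'
#' Vertex-wise mean over samples that share one parametrization, with
#' landmark-wise mean of the sample landmark sets.
#'
#' @param samples list of `palate_scan` objects (identical topology).
#' @param labels per-vertex region labels for the template.
#' @param cleft_type cleft type tag carried on the template.
#' @return object of class `palate_template`: list with `mesh`, `labels`,
#'   `landmarks`, `cleft_type`.
#' @export
template_from_samples <- function(samples, labels = samples[[1]]$labels,
                                  cleft_type = samples[[1]]$params$cleft_type) {
  if (length(samples) < 1L) stop("need at least one sample")
  F0 <- samples[[1]]$mesh$faces
  for (s in samples) {
    if (!identical(dim(s$mesh$vertices), dim(samples[[1]]$mesh$vertices)) ||
        !identical(s$mesh$faces, F0))
      stop("samples must share an identical topology")
  }
  V <- Reduce(`+`, lapply(samples, function(s) s$mesh$vertices)) /
    length(samples)
  L <- Reduce(`+`, lapply(samples, function(s) s$landmarks$positions)) /
    length(samples)
  out <- list(mesh = tri_mesh(V, F0), labels = labels,
              landmarks = landmark_set(L), cleft_type = cleft_type)
  class(out) <- "palate_template"
  out
}

#' Build a labeled template by averaging synthetic palates
#'
#' Mirrors how clinical templates are built: several palatal meshes of one
#' cleft type, generated on the shared parametric grid, are averaged
#' vertex-wise; landmarks are averaged likewise and region labels come
#' from the shared parametrization. For UCLP the template geometry is the
#' isolated healthy-ridge palate, with the would-be alveolar gap sector
#' labeled `bridge` so registration can span the cleft; for BCLP the
#' template keeps its two gaps and no bridge.
#'
#' @param cleft_type `"UCLP"`, `"BCLP"` or `"ISOLATED_HEALTHY_RIDGE"`.
#' @param n_samples number of synthetic palates averaged (>= 1).
#' @param seed integer seed.
#' @param params optional [palate_params()] overriding the defaults
#'   (its `cleft_type` must match).
#' @return a `palate_template` (see [template_from_samples()]).
#' @export
generate_template <- function(cleft_type = c("UCLP", "BCLP",
                                             "ISOLATED_HEALTHY_RIDGE"),
                              n_samples = 5, seed = 1, params = NULL) {
  cleft_type <- match.arg(cleft_type)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (is.null(params)) params <- palate_params(cleft_type, seed = seed)
  if (params$cleft_type != cleft_type) stop("params cleft_type mismatch")
  healthy <- cleft_type != "BCLP"
  samples <- lapply(seq_len(n_samples), function(k) {
    p <- params
    p$seed <- as.integer(params$seed + 7L * k)
    p$noise_sd <- 0
    p$rigid_pose <- NULL
    generate_palate_core(p, healthy = healthy, label_kind = "template")
  })
  template_from_samples(samples)
}

#' @export
print.palate_template <- function(x, ...) {
  cat(sprintf("palate_template (%s): %d vertices, %d faces\n", x$cleft_type,
              nrow(x$mesh$vertices), nrow(x$mesh$faces)))
  print(table(x$labels))
  invisible(x)
}

#' Derive a test scan from a template with known dense correspondence
#'
#' Applies a random smooth low-frequency displacement (scaled so its
#' maximum equals `deform_magnitude`), per-vertex noise along the normals
#' and an optional rigid pose; labels and landmarks are carried along, so
#' vertex i of the result corresponds to vertex i of the template.
#'
#' @param template a `palate_template`.
#' @param deform_magnitude maximum smooth displacement (mm).
#' @param noise_sd per-vertex noise standard deviation (mm).
#' @param pose optional [rigid_transform()].
#' @param seed integer seed.
#' @return a `palate_scan` with the template's labels.
#' @export
make_scan_from_template <- function(template, deform_magnitude = 2,
                                    noise_sd = 0.05, pose = NULL, seed = 1) {
  stopifnot(inherits(template, "palate_template"))
  V <- template$mesh$vertices
  L <- template$landmarks$positions
  mesh <- template$mesh
  with_seed(seed, {
    if (deform_magnitude > 0) {
      field <- random_smooth_field(deform_magnitude, V)
      V <- V + field(V)
      L <- L + field(L)
    }
    mesh <- tri_mesh(V, template$mesh$faces)
    if (noise_sd > 0) {
      N <- vertex_normals(mesh)
      mesh$vertices <- mesh$vertices + noise_sd * stats::rnorm(nrow(V)) * N
    }
  })
  if (!is.null(pose)) {
    mesh <- apply_transform(mesh, pose)
    L <- apply_transform(L, pose)
  }
  out <- list(mesh = mesh, landmarks = landmark_set(L),
              labels = template$labels,
              params = list(cleft_type = template$cleft_type, seed = seed,
                            deform_magnitude = deform_magnitude,
                            noise_sd = noise_sd, pose = pose))
  class(out) <- "palate_scan"
  out
}
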