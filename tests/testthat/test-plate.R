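test_that("cutting with every region selected returns the whole mesh", {
  rp <- fix_regpair()
  cut <- cut_plate_area(rp$registered, regions = palate_region_names())
  expect_identical(nrow(cut$mesh$vertices),
                   nrow(rp$registered$mesh$vertices))
  expect_identical(nrow(cut$mesh$faces), nrow(rp$registered$mesh$faces))
})

test_that("the cut keeps exactly the faces inside the selected regions", {
  rp <- fix_regpair()
  cut <- cut_plate_area(rp$registered, regions = "plate_area",
                        check_single_component = FALSE)
  lab <- rp$registered$labels
  F <- rp$registered$mesh$faces
  inset <- lab[F[, 1]] == "plate_area" & lab[F[, 2]] == "plate_area" &
    lab[F[, 3]] == "plate_area"
  expect_identical(nrow(cut$mesh$faces), sum(inset))
})

test_that("the default plate area is one component with one boundary loop", {
  rp <- fix_regpair()
  cut <- cut_plate_area(rp$registered)
  expect_identical(max(vertex_components(cut$mesh)), 1L)
  expect_identical(cut$n_boundary_loops, 1L)
})

test_that("the sphere fit recovers exact sphere samples", {
  set.seed(21)
  cen <- c(3, -2, 7)
  dirs <- matrix(rnorm(90), 30, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  anchors <- sweep(12 * dirs, 2, cen, "+")
  s <- fit_sphere(anchors)
  expect_lt(max(abs(s$center - cen)), 1e-6)
  expect_lt(abs(s$radius - 12), 1e-6)
})

test_that("the safety constraint is honoured and tight", {
  set.seed(22)
  cen <- c(0, 0, 0)
  dirs <- matrix(rnorm(90), 30, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  anchors <- sweep(12 * dirs, 2, cen, "+")
  # tissue 1 mm outside the unconstrained sphere: must push it inwards
  tissue <- matrix(c(13, 0, 0, 0, 13, 0), 2, 3, byrow = TRUE)
  s <- fit_sphere(anchors, tissue, safety_distance = 2.5)
  clear <- min(sqrt(rowSums(sweep(tissue, 2, s$center)^2))) - s$radius
  expect_gte(clear, 2.5 - 1e-4)
  expect_lte(clear, 2.5 + 0.05)   # tight at the solver tolerance
  expect_true(s$constraint_active)
})

test_that("safety distance zero reproduces the unconstrained fit", {
  set.seed(23)
  dirs <- matrix(rnorm(60), 20, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  anchors <- sweep(9 * dirs, 2, c(1, 2, 3), "+")
  tissue <- matrix(rnorm(30, sd = 30), 10, 3)
  a <- fit_sphere(anchors, tissue, safety_distance = 0)
  b <- fit_sphere(anchors)
  expect_lt(max(abs(a$center - b$center)), 1e-6)
  expect_lt(abs(a$radius - b$radius), 1e-6)
})

test_that("filling leaves non-cleft vertices bitwise unchanged", {
  rp <- fix_regpair()
  cut <- cut_plate_area(rp$registered)
  sph <- fit_cleft_sphere(rp$registered, 2.5)
  filled <- fill_cleft(cut$mesh, cut$labels, sph)
  keep <- cut$labels != "cleft_palate"
  expect_identical(filled$vertices[keep, ], cut$mesh$vertices[keep, ])
})

test_that("the fill hugs the fitted sphere", {
  # pipeline sphere on a genuine UCLP fixture (constraint shapes it)
  fit <- fix_fit7()
  reg <- fit$registered
  cut <- cut_plate_area(reg)
  sph <- fit$plate$sphere
  cleft <- which(cut$labels == "cleft_palate")
  notb <- setdiff(cleft, boundary_vertices(cut$mesh))
  # pure radial projection: exactly on the sphere
  f0 <- fill_cleft(cut$mesh, cut$labels, sph, relax_iterations = 0,
                   blend_hops = 0)
  dev0 <- abs(sqrt(rowSums(sweep(f0$vertices[notb, , drop = FALSE], 2,
                                 sph$center)^2)) - sph$radius)
  expect_lt(max(dev0), 1e-9)
  # after the default relaxation the interior stays within 0.5 mm
  f1 <- fill_cleft(cut$mesh, cut$labels, sph, relax_iterations = 5,
                   blend_hops = 0)
  interior <- notb[vapply(vertex_adjacency(cut$mesh)[notb], function(nb)
    all(cut$labels[nb] == "cleft_palate"), TRUE)]
  dev1 <- abs(sqrt(rowSums(sweep(f1$vertices[interior, , drop = FALSE], 2,
                                 sph$center)^2)) - sph$radius)
  expect_lt(stats::quantile(dev1, 0.9), 0.5)
})

test_that("the filled region keeps the safety distance to the tissue", {
  fit <- fix_fit7()
  expect_gte(fit$plate$report$clearance, 2.5)
})

test_that("a flat plane is a fixed point of convex smoothing", {
  p <- mesh_plane(9, 9)
  out <- convex_smooth(p, iterations = 5, damping = 0.7)
  expect_lt(max(abs(out$vertices - p$vertices)), 1e-9)
})

test_that("a bump toward the scan shrinks strictly each pass", {
  # the plane's normals (+z) are the offset direction, away from the
  # scan; a hemispherical bump toward the scan therefore dips along -z
  # and is exactly what an offset would fold over
  p <- mesh_plane(21, 21, width = 20, height = 20)
  r2 <- rowSums(p$vertices[, 1:2]^2)
  p$vertices[, 3] <- ifelse(r2 < 25, -sqrt(pmax(25 - r2, 0)), 0)
  h <- max(-p$vertices[, 3])  # bump height toward the scan
  cur <- p
  for (k in 1:4) {
    cur <- convex_smooth(cur, 1, 0.5)
    hn <- max(-cur$vertices[, 3])
    expect_lt(hn, h)
    h <- hn
  }
})

test_that("the interior of a dimple away from the scan is untouched", {
  # a depression away from the scan (+z): only its base ring is a valley
  # with respect to the offset direction; the cap itself must not move
  p <- mesh_plane(21, 21, width = 20, height = 20)
  r2 <- rowSums(p$vertices[, 1:2]^2)
  p$vertices[, 3] <- ifelse(r2 < 25, sqrt(pmax(25 - r2, 0)), 0)
  out <- convex_smooth(p, iterations = 3, damping = 0.5)
  cap <- r2 < 16
  expect_lt(max(abs(out$vertices[cap, ] - p$vertices[cap, ])), 1e-9)
})

test_that("convex smoothing is idempotent on its fixed points", {
  p <- mesh_plane(15, 15)
  once <- convex_smooth(p, 1, 0.5)
  twice <- convex_smooth(once, 1, 0.5)
  expect_lt(max(abs(twice$vertices - once$vertices)), 1e-9)
})

test_that("offsetting displaces exactly along the normals", {
  p <- mesh_plane(8, 8)
  off <- offset_surface(p, 0.7)
  expect_equal(off$vertices[, 3], rep(0.7, nrow(p$vertices)),
               tolerance = 1e-12)
  expect_identical(off$vertices[, 1:2], p$vertices[, 1:2])
  s <- mesh_icosphere(3, radius = 10)
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  off2 <- offset_surface(s, 2, normals = radial)
  expect_lt(max(abs(sqrt(rowSums(off2$vertices^2)) - 12)), 1e-6)
  # with computed area-weighted normals the radii are near-exact too
  off3 <- offset_surface(s, 2)
  expect_lt(max(abs(sqrt(rowSums(off3$vertices^2)) - 12)), 0.05)
})

test_that("two parallel disks volumize into the analytic solid", {
  contact <- disk_mesh(n = 36, radius = 5, z = 0)
  outer <- disk_mesh(n = 36, radius = 5, z = 2)
  pp <- plate_params(rim_samples = 8)
  solid <- volumize(contact, outer, pp)
  rep <- validate_mesh(solid)
  expect_true(rep$is_watertight)
  expect_identical(rep$self_intersection_count, 0L)
  # rim ring vertices sit on the sampled half-ellipse
  nV <- nrow(contact$vertices)
  nb <- 36L
  v1 <- solid$vertices[2L * nV + seq_len(nb), , drop = FALSE]  # ring j=1
  th <- pi / 8
  # boundary pair (0,0,0)-(0,0,2) family: mid z=1, separation 2, bulge 1
  z_expect <- 1 - cos(th) / 2 * 2
  r_expect <- 5 + 1 * sin(th)
  expect_lt(max(abs(v1[, 3] - z_expect)), 1e-6)
  expect_lt(max(abs(sqrt(rowSums(v1[, 1:2]^2)) - r_expect)), 1e-6)
  # enclosed volume: disk column plus the rim bulge
  vol <- abs(signed_volume(solid))
  disk_area <- pi * 5^2 * (36 / (2 * pi)) * sin(2 * pi / 36)
  expect_gt(vol, disk_area * 2)
  expect_lt(vol, disk_area * 2 + 2 * pi * 5 * (pi * 1 * 1 / 2) * 1.1)
})

test_that("a single rim sample degenerates to a straight watertight wall", {
  contact <- disk_mesh(n = 20, radius = 4, z = 0)
  outer <- disk_mesh(n = 20, radius = 4, z = 2)
  solid <- volumize(contact, outer, plate_params(rim_samples = 1))
  rep <- validate_mesh(solid)
  expect_true(rep$is_watertight)
  expect_identical(rep$self_intersection_count, 0L)
  expect_identical(nrow(solid$vertices), 2L * nrow(contact$vertices))
})

test_that("mismatched copies are rejected", {
  contact <- disk_mesh(n = 20)
  outer <- disk_mesh(n = 24)
  expect_error(volumize(contact, outer), "topology")
})

test_that("plate_report measures an exact plane offset construction", {
  ref <- mesh_plane(10, 10)
  contact <- offset_surface(ref, 0.1)
  rep <- plate_report(contact, ref, mask = seq_len(100))
  expect_equal(rep$mean, 0.1, tolerance = 1e-6)
  expect_lt(rep$sd, 1e-6)
  expect_identical(rep$frac_below, 0)
  expect_error(plate_report(contact, ref, integer(0)), "empty")
})

test_that("increasing the safety distance never reduces the clearance", {
  tpl <- fix_template()
  scan <- fix_scan7()
  fit25 <- fix_fit7()
  fit35 <- compute_plate(scan, tpl, plate = plate_params(safety_distance = 3.5))
  expect_gte(fit35$plate$report$clearance + 1e-9,
             fit25$plate$report$clearance)
  expect_gte(fit35$plate$report$clearance, 3.5)
})
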