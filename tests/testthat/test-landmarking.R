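test_that("proximity maps follow the exponential fall-off exactly", {
  V <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 5, 0), c(10, 0, 3))
  F <- rbind(c(1, 2, 3), c(2, 4, 3))
  mesh <- tri_mesh(V, F)
  L <- matrix(0, 10, 3)  # all landmarks on vertex 1
  maps <- build_target_maps(mesh, landmark_set(L))
  expect_equal(unname(maps$scores[1, 1]), 1)                   # exp(0)
  expect_equal(unname(maps$scores[2, 1]), exp(-1),
               tolerance = 1e-12)                              # 2 mm away
  expect_true(all(maps$scores > 0 & maps$scores <= 1))
})

test_that("maps are invariant under rigid motion of mesh and landmarks", {
  scan <- generate_palate(coarse_params(seed = 3))
  m0 <- build_target_maps(scan$mesh, scan$landmarks)
  set.seed(4)
  tf <- rigid_transform(random_rotation(), c(20, -5, 3))
  m1 <- build_target_maps(apply_transform(scan$mesh, tf),
                          landmark_set(apply_transform(
                            scan$landmarks$positions, tf)))
  expect_lt(max(abs(m0$scores - m1$scores)), 1e-12)
})

test_that("extraction recovers vertex-snapped landmarks exactly", {
  scan <- generate_palate(coarse_params(seed = 6))
  # snap landmarks onto mesh vertices
  idx <- apply(scan$landmarks$positions, 1, function(l)
    which.min(colSums((t(scan$mesh$vertices) - l)^2)))
  snapped <- landmark_set(scan$mesh$vertices[idx, , drop = FALSE])
  maps <- build_target_maps(scan$mesh, snapped)
  got <- extract_landmarks(maps, scan$mesh)
  expect_identical(unname(attr(got, "vertex")), unname(idx))
  expect_equal(got$positions, snapped$positions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(got$probabilities, rep(1, 10))
})

test_that("off-vertex landmarks are recovered at the nearest vertex", {
  scan <- generate_palate(coarse_params(seed = 7))
  maps <- build_target_maps(scan$mesh, scan$landmarks)
  got <- extract_landmarks(maps, scan$mesh)
  # oracle: brute-force nearest vertex
  near <- apply(scan$landmarks$positions, 1, function(l)
    which.min(colSums((t(scan$mesh$vertices) - l)^2)))
  expect_identical(unname(attr(got, "vertex")), unname(near))
  err <- sqrt(rowSums((got$positions - scan$landmarks$positions)^2))
  expect_lt(max(err), edge_lengths(scan$mesh)[["max"]])
})

test_that("argmax ties break toward the lowest vertex index", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  mesh <- tri_mesh(V, rbind(c(1, 2, 3), c(2, 4, 3)))
  S <- matrix(0.2, 4, 10)
  S[2, 1] <- 0.9
  S[4, 1] <- 0.9  # tie in column 1
  got <- extract_landmarks(segmentation_maps(S), mesh)
  expect_identical(attr(got, "vertex")[[1]], 2L)
})

test_that("certainty clamps raw scores into [0, 1]", {
  S <- matrix(0.5, 6, 10)
  S[3, ] <- 0.8
  nc <- normalize_certainty(segmentation_maps(S))
  expect_equal(unname(nc$certainty), rep(0.8, 10))  # in-range: column max
  expect_equal(nc$maps$scores, S, ignore_attr = TRUE)  # unchanged
  S2 <- S
  S2[3, 1] <- 1.7
  expect_equal(unname(normalize_certainty(
    segmentation_maps(S2))$certainty[1]), 1)
  S3 <- matrix(-0.2, 6, 10)
  expect_equal(unname(normalize_certainty(segmentation_maps(S3))$certainty),
               rep(0, 10))
})

test_that("the landmarker always emits exactly 10 landmarks", {
  scan <- generate_palate(coarse_params(seed = 8))
  maps <- build_target_maps(scan$mesh, scan$landmarks)
  got <- extract_landmarks(maps, scan$mesh)
  expect_identical(nrow(got$positions), 10L)
  expect_identical(length(got$names), 10L)
  expect_error(landmark_set(matrix(0, 9, 3)), "exactly 10")
})
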