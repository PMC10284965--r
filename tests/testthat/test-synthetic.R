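test_that("generation is bitwise deterministic given the seed", {
  a <- generate_palate(palate_params("UCLP", seed = 42))
  b <- generate_palate(palate_params("UCLP", seed = 42))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$landmarks$positions, b$landmarks$positions)
  c <- generate_palate(palate_params("UCLP", seed = 43))
  expect_false(identical(a$mesh$vertices, c$mesh$vertices))
})

test_that("the UCLP gap between ridge segments matches cleft_width", {
  for (seed in 1:5) {
    s <- generate_palate(palate_params("UCLP", cleft_width = 8, seed = seed))
    ridge <- which(s$labels == "alveolar_ridge")
    comp <- vertex_components(s$mesh, ridge)
    expect_identical(max(comp), 2L)
    parts <- split(ridge, comp)
    gap <- min(min_cross_distance(s$mesh$vertices[parts[[1]], ],
                                  s$mesh$vertices[parts[[2]], ]))
    expect_lt(abs(gap - 8), edge_lengths(s$mesh)[["mean"]])
  }
})

test_that("BCLP ridge decomposes into three segments around a premaxilla", {
  for (seed in 1:3) {
    s <- generate_palate(palate_params("BCLP", seed = seed))
    ridge <- which(s$labels == "alveolar_ridge")
    expect_identical(max(vertex_components(s$mesh, ridge)), 3L)
  }
})

test_that("every vertex is labeled and ridge area is positive for all types", {
  for (ct in c("UCLP", "BCLP", "ISOLATED_HEALTHY_RIDGE")) {
    s <- generate_palate(palate_params(ct, seed = 1))
    expect_false(anyNA(s$labels))
    expect_identical(length(s$labels), nrow(s$mesh$vertices))
    expect_gt(sum(s$labels == "alveolar_ridge"), 0)
  }
})

test_that("a centred BCLP landmark set is mirror-symmetric", {
  s <- generate_palate(palate_params("BCLP", cleft_position = 0.5,
                                     shape_variation = 0, noise_sd = 0))
  L <- s$landmarks$positions
  M <- L
  M[, 1] <- -M[, 1]
  perm <- c(2, 1, 4, 3, 6, 5, 7, 8, 10, 9)  # swap left/right names
  expect_lt(max(abs(L[perm, ] - M)), 1e-9)
})

test_that("a template from one sample equals that sample", {
  s <- generate_palate(coarse_params(seed = 5))
  tpl <- template_from_samples(list(s))
  expect_identical(tpl$mesh$vertices, s$mesh$vertices)
  expect_identical(tpl$landmarks$positions, s$landmarks$positions)
})

test_that("template averaging halves a vault-depth difference", {
  pA <- palate_params("ISOLATED_HEALTHY_RIDGE", vault_depth = 6,
                      shape_variation = 0, noise_sd = 0)
  pB <- palate_params("ISOLATED_HEALTHY_RIDGE", vault_depth = 8,
                      shape_variation = 0, noise_sd = 0)
  tpl <- template_from_samples(list(generate_palate(pA),
                                    generate_palate(pB)))
  expect_equal(max(tpl$mesh$vertices[, 3]), 7, tolerance = 1e-9)
})

test_that("template landmarks are the exact mean of sample landmarks", {
  samples <- lapply(1:3, function(k)
    generate_palate(coarse_params(seed = 10 + k)))
  tpl <- template_from_samples(samples)
  mean_lm <- Reduce(`+`, lapply(samples, function(s)
    s$landmarks$positions)) / 3
  expect_equal(tpl$landmarks$positions, mean_lm, tolerance = 1e-12)
})

test_that("template averaging is permutation invariant", {
  samples <- lapply(1:4, function(k)
    generate_palate(coarse_params(seed = 20 + k)))
  t1 <- template_from_samples(samples)
  t2 <- template_from_samples(samples[c(3, 1, 4, 2)])
  expect_equal(t1$mesh$vertices, t2$mesh$vertices, tolerance = 1e-12)
})

test_that("mixed topologies cannot be averaged", {
  a <- generate_palate(coarse_params(seed = 1))
  b <- generate_palate(palate_params("UCLP", n_arc = 40, n_rad = 15))
  expect_error(template_from_samples(list(a, b)), "topology")
})

test_that("make_scan_from_template honours its contracts", {
  tpl <- fix_template_coarse()
  # zero deformation, noise and pose: exact copy
  sc0 <- make_scan_from_template(tpl, 0, 0, NULL, seed = 1)
  expect_identical(sc0$mesh$vertices, tpl$mesh$vertices)
  expect_identical(sc0$labels, tpl$labels)
  # pure rigid pose is exactly invertible
  set.seed(8)
  pose <- rigid_transform(random_rotation(), c(5, -3, 11))
  scp <- make_scan_from_template(tpl, 0, 0, pose, seed = 1)
  back <- apply_transform(scp$mesh, invert_transform(pose))
  expect_lt(max(abs(back$vertices - tpl$mesh$vertices)), 1e-9)
  # deformation magnitude bounds the maximum displacement
  scd <- make_scan_from_template(tpl, 3, 0, NULL, seed = 2)
  d <- sqrt(rowSums((scd$mesh$vertices - tpl$mesh$vertices)^2))
  expect_lte(max(d), 3 + 1e-9)
  expect_gt(max(d), 1)  # the field is actually applied
})

test_that("invalid parameters are rejected", {
  expect_error(palate_params("UCLP", cleft_width = 50), "cleft_width")
  expect_error(palate_params("UCLP", vault_depth = -1), "positive")
  expect_error(palate_params("UCLP", cleft_position = 1.2), "cleft_position")
})
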