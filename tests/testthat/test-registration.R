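test_that("cycle 2 keeps the ridge vertices at their cycle-1 positions", {
  rp <- fix_regpair()
  tpl <- rp$template
  lm <- rp$scan$landmarks
  lm$probabilities <- rep(1, 10)
  ridge <- tpl$labels == "alveolar_ridge"
  cycle1 <- nicp(tpl$mesh, rp$scan$mesh, active = ridge,
                 landmarks = rp$registered$landmark_pairs)
  expect_lt(max(abs(rp$registered$mesh$vertices[ridge, ] -
                    cycle1$vertices[ridge, ])), 1e-9)
})

test_that("the bridge region carries no data term", {
  rp <- fix_regpair()
  expect_gt(sum(rp$template$labels == "bridge"), 0)
  expect_false(any(rp$registered$active1[rp$template$labels == "bridge"]))
  expect_false(any(rp$registered$active2[rp$template$labels == "bridge"]))
})

test_that("ridge correspondence error stays below 0.5 mm", {
  rp <- fix_regpair()
  ridge <- rp$template$labels == "alveolar_ridge"
  err <- sqrt(rowSums((rp$registered$mesh$vertices[ridge, ] -
                       rp$scan$mesh$vertices[ridge, ])^2))
  expect_lt(mean(err), 0.5)
})

test_that("label transfer agrees with ground truth on >= 95% of vertices", {
  rp <- fix_regpair()
  reg <- rp$registered
  cp <- closest_points(reg$mesh$vertices, rp$scan$mesh)
  corner <- max.col(cp$bary)
  vid <- rp$scan$mesh$faces[cbind(cp$tri, corner)]
  agree <- mean(as.character(transfer_segmentation(reg)) ==
                as.character(rp$scan$labels[vid]))
  expect_gte(agree, 0.95)
})

test_that("the transferred label multiset equals the template's", {
  rp <- fix_regpair()
  expect_identical(table(transfer_segmentation(rp$registered)),
                   table(rp$template$labels))
})

test_that("registered ridge vertices lie on the scan surface", {
  rp <- fix_regpair()
  ridge <- which(rp$template$labels == "alveolar_ridge")
  sdf <- signed_point_to_plane_distance(rp$registered$mesh,
                                        rp$scan$mesh, mask = ridge)
  expect_lt(mean(abs(sdf$distances)), 0.5)
})

test_that("the registered ridge-plus-bridge band spans the cleft gap", {
  # register the bridging template onto a genuine UCLP scan (not
  # template-derived): the band must stay a single connected component
  # even though the scan's ridge has an 8 mm gap
  tpl <- fix_template()
  fit <- fix_fit7()
  band <- which(tpl$labels %in% c("alveolar_ridge", "bridge"))
  comp <- vertex_components(fit$registered$mesh, band)
  expect_identical(max(comp), 1L)
  # and the bridge hangs near the chord between the anterior margins
  lm <- fit$registered$mesh$vertices
  mL <- tpl$landmarks$positions["cleft_margin_ant_L", ]
  mR <- tpl$landmarks$positions["cleft_margin_ant_R", ]
  bridge <- which(tpl$labels == "bridge")
  chord_mid <- (mL + mR) / 2
  d <- sqrt(rowSums(sweep(lm[bridge, , drop = FALSE], 2, chord_mid)^2))
  expect_lt(max(d), sqrt(sum((mL - mR)^2)))  # within the margin span
})
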