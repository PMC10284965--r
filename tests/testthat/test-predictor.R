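# a small training cohort on the coarse grid, built once
fix_dataset <- function() {
  fixture("train_ds", lapply(1:16, function(k)
    generate_palate(coarse_params(seed = 100 + k))))
}

fix_predictors <- function() {
  fixture("trained_predictors", {
    ds <- fix_dataset()
    list(stage1 = train_predictor(ds, stage = 1, seed = 5),
         stage2 = train_predictor(ds, stage = 2, seed = 6))
  })
}

test_that("training reduces the MSE below the untrained baseline", {
  ds <- fix_dataset()
  p1 <- fix_predictors()$stage1
  baseline <- mean(vapply(ds, function(d)
    mean(build_target_maps(d$mesh, d$landmarks)$scores^2), 0))
  expect_lt(p1$train_mse, baseline)
  expect_lt(p1$test_mse, baseline)
})

test_that("training is reproducible given the seed", {
  ds <- fix_dataset()[1:6]
  a <- train_predictor(ds, stage = 2, seed = 9, n_augment = 2)
  b <- train_predictor(ds, stage = 2, seed = 9, n_augment = 2)
  expect_identical(a$weights, b$weights)
  expect_identical(a$train_mse, b$train_mse)
})

test_that("stage-2 training rotations stay within +/- 0.2 rad azimuth", {
  p2 <- fix_predictors()$stage2
  expect_true(all(abs(p2$augment_angles) <= 0.2))
  expect_gt(length(p2$augment_angles), 0)
})

test_that("a dataset too small to split is rejected", {
  ds <- fix_dataset()[1]
  expect_error(train_predictor(ds, stage = 1), "too small")
})

test_that("two-stage prediction beats the raw stage-1 prediction", {
  pr <- fix_predictors()
  tpl <- fix_template_coarse()
  e1 <- numeric(0)
  e2 <- numeric(0)
  set.seed(9)
  for (k in 1:20) {
    pose <- rigid_transform(random_rotation(), rnorm(3, sd = 20))
    sc <- generate_palate(coarse_params(seed = 300 + k, rigid_pose = pose))
    res <- predict_two_stage(sc$mesh, pr$stage1, pr$stage2, tpl)
    truth_aligned <- apply_transform(sc$landmarks$positions, res$alignment)
    e2 <- c(e2, mean(sqrt(rowSums(
      (res$landmarks$positions - truth_aligned)^2))))
    e1 <- c(e1, mean(sqrt(rowSums(
      (res$stage1_landmarks$positions - sc$landmarks$positions)^2))))
  }
  expect_lt(mean(e2), mean(e1))
})

test_that("oracle two-stage recovers landmarks within one edge length", {
  tpl <- fix_template()
  for (k in 1:3) {
    set.seed(40 + k)
    pose <- rigid_transform(random_rotation(), rnorm(3, sd = 25))
    sc <- generate_palate(palate_params("UCLP", seed = 50 + k,
                                        rigid_pose = pose))
    res <- predict_two_stage(sc$mesh, oracle_predictor(1),
                             oracle_predictor(2), tpl,
                             landmarks = sc$landmarks)
    truth_aligned <- apply_transform(sc$landmarks$positions, res$alignment)
    err <- sqrt(rowSums((res$landmarks$positions - truth_aligned)^2))
    # quantization bound: the nearest-vertex snap
    expect_lt(mean(err), edge_lengths(sc$mesh)[["mean"]])
  }
})

test_that("aligned-frame landmarks map back onto the input mesh surface", {
  tpl <- fix_template_coarse()
  set.seed(77)
  pose <- rigid_transform(random_rotation(), c(9, -4, 2))
  sc <- generate_palate(coarse_params(seed = 66, rigid_pose = pose))
  res <- predict_two_stage(sc$mesh, oracle_predictor(1),
                           oracle_predictor(2), tpl,
                           landmarks = sc$landmarks)
  back <- apply_transform(res$landmarks$positions,
                          invert_transform(res$alignment))
  d <- closest_points(back, sc$mesh)$dist
  expect_lt(max(d), 1e-6)
})

test_that("oracle predictors require ground-truth landmarks", {
  sc <- generate_palate(coarse_params(seed = 1))
  expect_error(predict(oracle_predictor(1), sc$mesh), "ground-truth")
})
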