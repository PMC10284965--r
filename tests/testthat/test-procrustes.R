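make_points <- function(seed = 1) {
  set.seed(seed)
  matrix(rnorm(30, sd = 8), 10, 3)
}

test_that("weighted Procrustes recovers a noiseless similarity exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    S <- make_points(seed)
    R <- random_rotation()
    s <- runif(1, 0.7, 1.4)
    t <- rnorm(3, sd = 15)
    T_ <- sweep(s * S %*% t(R), 2, t, "+")
    tf <- weighted_procrustes(S, T_)
    expect_lt(max(abs(apply_transform(S, tf) - T_)), 1e-9)
    expect_equal(tf$scale, s, tolerance = 1e-9)
  }
})

test_that("a grossly displaced landmark with zero weight has no effect", {
  S <- make_points(3)
  R <- random_rotation()
  T_ <- sweep(S %*% t(R), 2, c(4, -2, 9), "+")
  S_bad <- S
  S_bad[4, ] <- S_bad[4, ] + 50
  w <- rep(1, 10)
  w[4] <- 0
  tf_w <- weighted_procrustes(S_bad, T_, weights = w)
  expect_lt(max(abs(apply_transform(S_bad, tf_w)[-4, ] - T_[-4, ])), 1e-9)
  # the unweighted fit must differ
  tf_u <- weighted_procrustes(S_bad, T_)
  expect_gt(max(abs(apply_transform(S_bad, tf_u)[-4, ] - T_[-4, ])), 0.1)
})

test_that("source equal to target yields the identity transform", {
  S <- make_points(2)
  tf <- weighted_procrustes(S, S)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tf$translation)), 1e-9)
  expect_equal(tf$scale, 1, tolerance = 1e-9)
})

test_that("degenerate configurations are rejected", {
  S <- make_points(1)
  T_ <- S
  w <- c(1, 1, rep(0, 8))
  expect_error(weighted_procrustes(S, T_, weights = w), "degenerate")
  line <- cbind(seq_len(10), 2 * seq_len(10), -seq_len(10))
  expect_error(weighted_procrustes(line, line), "collinear")
})

test_that("downweighting the worst landmark never increases the residual", {
  set.seed(11)
  for (rep in 1:5) {
    S <- make_points(rep)
    R <- random_rotation()
    T_ <- sweep(S %*% t(R), 2, rnorm(3, sd = 5), "+") +
      matrix(rnorm(30, sd = 0.5), 10, 3)
    w <- rep(1, 10)
    resid <- function(w) {
      tf <- weighted_procrustes(S, T_, weights = w, scale = FALSE)
      sum(w * rowSums((apply_transform(S, tf) - T_)^2))
    }
    r0 <- resid(w)
    tf0 <- weighted_procrustes(S, T_, weights = w, scale = FALSE)
    worst <- which.max(rowSums((apply_transform(S, tf0) - T_)^2))
    for (f in c(0.7, 0.4, 0.1)) {
      w2 <- w
      w2[worst] <- f
      expect_lte(resid(w2), r0 + 1e-12)
    }
  }
})
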