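lab <- function(n, p) paste0(p, seq_len(n))

test_that("column normalization is stochastic on nonzero columns only", {
  W <- matrix(c(2, 2, 0, 0), 2, dimnames = list(lab(2, "d"), lab(2, "d")))
  M <- column_normalize(W)
  expect_equal(M[, 1], c(d1 = 0.5, d2 = 0.5))
  expect_equal(M[, 2], c(d1 = 0, d2 = 0))   # isolated column stays zero

  set.seed(2)
  for (trial in 1:10) {
    W2 <- matrix(runif(25), 5) * rbinom(25, 1, 0.6)
    dimnames(W2) <- list(lab(5, "e"), lab(5, "e"))
    M2 <- column_normalize(W2)
    cs <- colSums(M2)
    expect_true(all(abs(cs - 1) < 1e-12 | cs == 0))
  }
  neg <- matrix(c(1, -0.1, 0, 1), 2)
  expect_error(column_normalize(neg), "nonnegative")
})

test_that("single walk steps obey their closed forms", {
  set.seed(5)
  P <- matrix(runif(12), 3, 4)
  MD <- column_normalize(matrix(runif(16), 4, 4,
                                dimnames = list(lab(4, "d"), lab(4, "d"))))
  ML <- column_normalize(matrix(runif(9), 3, 3,
                                dimnames = list(lab(3, "l"), lab(3, "l"))))
  Y0 <- matrix(runif(12), 3, 4)

  expect_equal(walk_step_disease(P, MD, Y0, alpha = 1), Y0,
               ignore_attr = TRUE)
  expect_equal(walk_step_lnc(P, ML, Y0, alpha = 1), Y0,
               ignore_attr = TRUE)
  expect_equal(walk_step_disease(P, diag(4), Y0, alpha = 0), P)
  expect_equal(walk_step_lnc(P, diag(3), Y0, alpha = 0), P)
  expect_equal(walk_step_disease(P, MD, Y0, 0.9),
               0.1 * P %*% MD + 0.9 * Y0)
  expect_equal(walk_step_lnc(P, ML, Y0, 0.9),
               0.1 * ML %*% P + 0.9 * Y0)
  expect_error(walk_step_disease(P, ML, Y0, 0.9), "mismatch")
})

test_that("identity networks leave the normalized start matrix fixed", {
  Y <- random_Y(4, 3, seed = 7)
  I_d <- diag(3); dimnames(I_d) <- list(colnames(Y), colnames(Y))
  I_l <- diag(4); dimnames(I_l) <- list(rownames(Y), rownames(Y))
  for (caps in list(c(1, 0), c(3, 1), c(2, 2))) {
    F_ <- unbalanced_birandom_walk(Y, I_d, I_l, alpha = 0.9,
                                   s1 = caps[1], s2 = caps[2])
    expect_equal(F_, Y / sum(Y))
  }
})

test_that("a single disease step equals its hand formula, alpha = 1 restarts", {
  Y <- random_Y(4, 3, seed = 9)
  set.seed(10)
  MD <- column_normalize(matrix(runif(9), 3, 3,
                                dimnames = list(colnames(Y), colnames(Y))))
  ML <- column_normalize(matrix(runif(16), 4, 4,
                                dimnames = list(rownames(Y), rownames(Y))))
  P0 <- unclass(Y) / sum(Y)
  F_ <- unbalanced_birandom_walk(Y, MD, ML, alpha = 0.9, s1 = 1, s2 = 0)
  expect_equal(F_, 0.1 * P0 %*% MD + 0.9 * P0, ignore_attr = FALSE)

  F_restart <- unbalanced_birandom_walk(Y, MD, ML, alpha = 1, s1 = 3, s2 = 2)
  expect_equal(F_restart, P0)
})

test_that("a 2x2 toy with s1 = s2 = 1 averages the two one-step updates", {
  Y <- association_matrix(matrix(c(1, 0, 0, 1), 2),
                          c("l1", "l2"), c("dA", "dB"))
  MD <- matrix(c(0.75, 0.25, 0.5, 0.5), 2,
               dimnames = list(colnames(Y), colnames(Y)))
  ML <- matrix(c(0.4, 0.6, 0.3, 0.7), 2,
               dimnames = list(rownames(Y), rownames(Y)))
  alpha <- 0.9
  P0 <- unclass(Y) / 2
  DP <- 0.1 * P0 %*% MD + 0.9 * P0
  LP <- 0.1 * ML %*% P0 + 0.9 * P0
  F_ <- unbalanced_birandom_walk(Y, MD, ML, alpha = alpha, s1 = 1, s2 = 1)
  expect_equal(unclass(F_), (DP + LP) / 2, ignore_attr = TRUE)
})

test_that("balanced caps on one shared network match an independent restart walk", {
  set.seed(33)
  n <- 5
  Y <- random_Y(n, n, seed = 12)
  labs <- rownames(Y)
  M <- column_normalize(matrix(runif(n * n), n, dimnames = list(labs, labs)))
  colnames(Y) <- labs   # square bipartite matrix over one label set
  Y <- association_matrix(unclass(Y), labs, labs)
  for (steps in 1:3) {
    F_ <- unbalanced_birandom_walk(Y, M, M, alpha = 0.7,
                                   s1 = steps, s2 = steps)
    P0 <- unclass(Y) / sum(Y)
    expect_equal(unclass(F_), balanced_rwr(P0, M, P0, 0.7, steps),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("walk output is finite, nonnegative and bitwise reproducible", {
  Y <- random_Y(6, 5, seed = 14)
  set.seed(15)
  MD <- column_normalize(matrix(runif(25), 5, 5,
                                dimnames = list(colnames(Y), colnames(Y))))
  ML <- column_normalize(matrix(runif(36), 6, 6,
                                dimnames = list(rownames(Y), rownames(Y))))
  F1 <- unbalanced_birandom_walk(Y, MD, ML, alpha = 0.9, s1 = 3, s2 = 1)
  F2 <- unbalanced_birandom_walk(Y, MD, ML, alpha = 0.9, s1 = 3, s2 = 1)
  expect_identical(F1, F2)
  expect_true(all(is.finite(F1)) && all(F1 >= 0))
  # total mass is bounded by start mass plus the restart injections
  expect_lte(sum(F1), sum(Y / sum(Y)) + 0.9 * 3 * sum(Y / sum(Y)) + 1e-12)

  zero <- association_matrix(matrix(0, 2, 2), c("l1", "l2"), c("dA", "dB"))
  Z <- diag(2)
  expect_error(unbalanced_birandom_walk(
    zero,
    matrix(Z, 2, dimnames = list(c("dA", "dB"), c("dA", "dB"))),
    matrix(Z, 2, dimnames = list(c("l1", "l2"), c("l1", "l2"))),
    alpha = 0.9, s1 = 1, s2 = 0), "all zero")
  expect_error(unbalanced_birandom_walk(Y, MD, ML, alpha = 0.9,
                                        s1 = 0, s2 = 0), "s1 \\+ s2")
})
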