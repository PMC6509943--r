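test_that("pair similarity matches hand-derived values", {
  D <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_equal(lncrna_similarity_pair(1, 1, D), 1.0)
  expect_equal(lncrna_similarity_pair(1, 2, D), 0.4)
  D2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  ## sets {d1,d2} vs {d1}: (1 + 0.5 + 1) / 3
  expect_equal(lncrna_similarity_pair(c(1, 2), 1, D2), (1 + 0.5 + 1) / 3)
})

test_that("empty disease sets give similarity 0, not an error", {
  D <- diag(1, 3)
  expect_equal(lncrna_similarity_pair(integer(), 1:2, D), 0)
  expect_equal(lncrna_similarity_pair(integer(), integer(), D), 0)
  expect_error(lncrna_similarity_pair(1, 1, matrix(-0.1, 1, 1)), "negative")
})

test_that("similarity matrix: symmetry, unit diagonal, known cases", {
  A <- rbind(c(1, 0), c(0, 1))
  L <- lncrna_similarity_matrix(A, diag(1, 2))
  expect_equal(L, diag(1, 2))

  ## identical rows give off-diagonal 1
  A2 <- rbind(c(1, 1, 0), c(1, 1, 0))
  L2 <- lncrna_similarity_matrix(A2, diag(1, 3))
  expect_equal(L2[1, 2], 1)

  ## all-zero row: similarity 0 off the diagonal, 1 on it
  A3 <- rbind(c(1, 0), c(0, 0))
  L3 <- lncrna_similarity_matrix(A3, diag(1, 2))
  expect_equal(L3, matrix(c(1, 0, 0, 1), 2, 2))

  expect_error(lncrna_similarity_matrix(A, diag(1, 3)), "mismatch")
})

test_that("matrix builder agrees with the brute-force evaluator on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    n_d <- sample(3:8, 1)
    n_l <- sample(2:6, 1)
    D <- matrix(runif(n_d^2), n_d)
    D <- (D + t(D)) / 2
    diag(D) <- 1
    A <- matrix(rbinom(n_l * n_d, 1, 0.4), n_l, n_d)
    L <- lncrna_similarity_matrix(A, D)
    for (i in seq_len(n_l)) {
      for (j in seq_len(n_l)) {
        expected <- if (i == j) 1 else
          oracle_set_similarity(which(A[i, ] == 1), which(A[j, ] == 1), D)
        expect_equal(L[i, j], expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("similarity is symmetric, bounded, and monotone in the cross term", {
  set.seed(7)
  D <- matrix(runif(25), 5); D <- (D + t(D)) / 2; diag(D) <- 1
  for (rep in 1:40) {
    a <- sample(5, sample(1:3, 1))
    b <- sample(5, sample(1:3, 1))
    s_ab <- lncrna_similarity_pair(a, b, D)
    expect_equal(s_ab, lncrna_similarity_pair(b, a, D), tolerance = 1e-12)
    expect_gte(s_ab, 0); expect_lte(s_ab, 1 + 1e-12)
  }
  ## singleton sets: raising the unique cross-similarity raises LS
  D_lo <- D; D_lo[1, 2] <- D_lo[2, 1] <- 0.2
  D_hi <- D; D_hi[1, 2] <- D_hi[2, 1] <- 0.8
  expect_lt(lncrna_similarity_pair(1, 2, D_lo), lncrna_similarity_pair(1, 2, D_hi))
})

test_that("training-only similarity never sees held-out positives", {
  net <- toy_network()
  pos <- which(net$A == 1, arr.ind = TRUE)
  ## full training set reproduces the stored similarity
  expect_equal(recompute_training_similarity(net, pos), unname(net$L),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## empty training set: identity
  expect_equal(recompute_training_similarity(net, pos[0, , drop = FALSE]),
               diag(1, 3))
  ## holding out one positive changes exactly the touched lncRNA's rows/cols
  held <- pos[1, , drop = FALSE]
  kept <- pos[-1, , drop = FALSE]
  L_train <- recompute_training_similarity(net, kept)
  A_train <- matrix(0, 3, 3); A_train[kept] <- 1
  L_oracle <- diag(1, 3)
  for (i in 1:3) for (j in 1:3) if (i != j)
    L_oracle[i, j] <- oracle_set_similarity(which(A_train[i, ] == 1),
                                            which(A_train[j, ] == 1), net$D)
  expect_equal(L_train, L_oracle, tolerance = 1e-12)
  touched <- held[1, 1]
  full_L <- unname(net$L)
  differs <- abs(L_train - full_L) > 1e-12
  expect_true(all(which(differs, arr.ind = TRUE)[, 1] == touched |
                  which(differs, arr.ind = TRUE)[, 2] == touched))
  ## a pair outside the support is a leakage error
  expect_error(recompute_training_similarity(net, rbind(c(2, 1))), "leakage")
})
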