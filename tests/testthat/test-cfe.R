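test_that("LDA weights point with the class difference and handle collinearity", {
  set.seed(51)
  n <- 100
  y <- rep(c(1, -1), each = n / 2)
  x <- rnorm(n, ifelse(y == 1, 2, -2), 1)
  clf <- train_lda(matrix(x, ncol = 1, dimnames = list(NULL, "f1")), y)
  expect_gt(clf$weights["f1"], 0)

  # duplicated feature: shrinkage keeps the problem well-posed and the
  # decision values match a pseudo-inverse solution up to ranking
  X2 <- cbind(f1 = x, f2 = x)
  clf2 <- train_lda(X2, y)
  expect_true(all(is.finite(clf2$weights)))
  d1 <- decision_values(clf, matrix(x, ncol = 1))
  d2 <- decision_values(clf2, X2)
  expect_equal(cor(d1, d2), 1, tolerance = 1e-6)

  # no signal -> held-out AUC near 0.5
  set.seed(52)
  Xn <- matrix(rnorm(200 * 4), ncol = 4)
  yn <- rep(c(1, -1), 100)
  clfn <- train_lda(Xn[1:150, ], yn[1:150])
  expect_lt(abs(auc(decision_values(clfn, Xn[151:200, ]),
                    yn[151:200]) - 0.5), 0.25)
})

test_that("linear SVM separates separable data and scales like the margin geometry", {
  X <- matrix(c(-1, 1), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(-1, 1)
  # two-point separable problem classified correctly (large cost)
  clf <- train_linear_svm(rbind(X, X), c(y, y), cost = 100)
  expect_true(all(sign(decision_values(clf, X)) == y))

  # scaling the features by 2 halves the weights for separable data
  set.seed(53)
  Xs <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
               dimnames = list(NULL, "f"))
  ys <- rep(c(-1, 1), each = 20)
  w1 <- train_linear_svm(Xs, ys, cost = 1000)$weights
  w2 <- train_linear_svm(Xs * 2, ys, cost = 1000)$weights
  expect_equal(unname(w2), unname(w1) / 2, tolerance = 1e-4)

  expect_error(train_linear_svm(Xs, rep(1, 40)), "both classes")
})

test_that("AUC equals the pair-counting oracle, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, -1, -1)), 1.0)
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1)), 0.75)
  expect_equal(auc(rep(0.4, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  set.seed(54)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    expect_equal(auc(scores, y), auc_oracle(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("consensus elimination finds a planted separating feature and is reproducible", {
  set.seed(55)
  n <- 60
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(signal = ifelse(y == 1, 1, -1) + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 7), ncol = 7,
                    dimnames = list(NULL, paste0("noise", 1:7))))
  r <- consensus_feature_elimination(X, y, n_splits = 20, seed = 101)
  expect_true("signal" %in% r$selected_features)
  expect_gte(r$max_mean_auc, 0.95)
  expect_equal(nrow(r$trajectory), ncol(X))     # full trajectory reported
  expect_true(all(r$trajectory$mean_auc >= 0 & r$trajectory$mean_auc <= 1))
  # bit-reproducible under a fixed seed
  r2 <- consensus_feature_elimination(X, y, n_splits = 20, seed = 101)
  expect_identical(r$trajectory, r2$trajectory)
  expect_identical(r$selected_features, r2$selected_features)
  # single feature: nothing to eliminate
  r1 <- consensus_feature_elimination(X[, 1, drop = FALSE], y,
                                      n_splits = 10, seed = 7)
  expect_equal(nrow(r1$trajectory), 1)
  expect_equal(r1$selected_features, "signal")
})

test_that("LDA and SVM agree on the sign of a strongly informative feature", {
  set.seed(56)
  n <- 80
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(s = ifelse(y == 1, 1.5, -1.5) + rnorm(n, 0, 0.4),
             n1 = rnorm(n))
  expect_gt(train_lda(X, y)$weights["s"], 0)
  expect_gt(train_linear_svm(X, y)$weights["s"], 0)
})

test_that("final marker selection is frequency-based with deterministic ties", {
  set.seed(57)
  n <- 50
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(sig = ifelse(y == 1, 2, -2),
             matrix(rnorm(n * 3), ncol = 3,
                    dimnames = list(NULL, paste0("z", 1:3))))
  sel <- select_final_markers(X, y, n_repeats = 5, n_splits = 10,
                              seed = 11)
  expect_true("sig" %in% sel$selected_features)
  expect_equal(unname(sel$feature_frequencies["sig"]), 1)
  expect_equal(sum(sel$set_frequencies$count), 5)
})
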