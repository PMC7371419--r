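test_that("class balancing removes only majority trials", {
  e <- toy_epochs(n_per_class = 50)
  e_unbal <- subset_trials(e, 1:90)          # 50 class-0, 40 class-1
  b <- balance_classes(e_unbal, seed = 1)
  expect_equal(sum(b$labels == 0L), 40L)
  expect_equal(sum(b$labels == 1L), 40L)
  # minority class untouched, retained trials a subset of the input
  expect_equal(sum(b$labels == 1L), sum(e_unbal$labels == 1L))
  expect_true(all(apply(b$data, 1, sum) %in% apply(e_unbal$data, 1, sum)))
  # already balanced: no-op
  expect_identical(balance_classes(e, seed = 1)$data, e$data)
  e1 <- subset_trials(e, 1:50)
  expect_error(balance_classes(e1, seed = 1), "both classes")
})

test_that("demeaning zeroes trial means and preserves class contrast", {
  e <- toy_epochs(seed = 3)
  d <- demean(e)
  mu <- colMeans(d$data)
  expect_lt(max(abs(mu)), 1e-10)
  diff_before <- colMeans(e$data[e$labels == 0L, , ]) -
    colMeans(e$data[e$labels == 1L, , ])
  diff_after <- colMeans(d$data[d$labels == 0L, , ]) -
    colMeans(d$data[d$labels == 1L, , ])
  expect_lt(max(abs(diff_before - diff_after)), 1e-10)
  # single trial becomes all zeros
  single <- subset_trials(e, 1)
  expect_lt(max(abs(demean(single)$data)), 1e-12)
})

test_that("shrinkage LDA matches the closed-form discriminant", {
  e <- toy_epochs(n_per_class = 40, n_sensors = 5, seed = 4, noise_sd = 0.5)
  m <- train_lda(e, 0.05, gamma = 0)
  # independent oracle: w = pooled-covariance inverse times mean difference
  idx <- which.min(abs(e$times - 0.05))
  x <- e$data[, , idx]
  mu0 <- colMeans(x[e$labels == 0L, ])
  mu1 <- colMeans(x[e$labels == 1L, ])
  s0 <- cov(x[e$labels == 0L, ]) * 39
  s1 <- cov(x[e$labels == 1L, ]) * 39
  w <- solve((s0 + s1) / 78, mu0 - mu1)
  expect_lt(max(abs(m$weights - w)) / max(abs(w)), 1e-8)
  expect_equal(m$bias, -sum(w * (mu0 + mu1)) / 2, tolerance = 1e-8)

  # default shrinkage recorded on the model
  expect_equal(train_lda(e, 0.05)$gamma, 0.05)

  # identical class means: zero discriminant
  e2 <- e
  e2$data[e2$labels == 1L, , ] <- e2$data[e2$labels == 0L, , ]
  m2 <- train_lda(e2, 0.05)
  expect_lt(max(abs(m2$weights)), 1e-10)
})

test_that("evidence is the sign-flipped distance to the hyperplane", {
  dat <- array(0, dim = c(2, 2, 4))
  dat[1, , ] <- c(2, 5)                       # class 0 trial, constant (2, 5)
  dat[2, , ] <- c(2, 5)                       # same pattern labelled class 1
  e <- epochs(dat, c(0L, 1L), c(1L, 1L), (0:3) / 300, 300)
  m <- structure(list(weights = c(1, 0), bias = 0, train_time = 0,
                      gamma = 0.05, fold = NA), class = "lda_model")
  ev <- evidence(m, e)
  expect_equal(unname(ev[1, ]), rep(2, 4))
  expect_equal(unname(ev[2, ]), rep(-2, 4))
  m0 <- structure(list(weights = c(0, 0), bias = 0, train_time = 0,
                       gamma = 0.05, fold = NA), class = "lda_model")
  expect_true(all(evidence(m0, e) == 0))
})

test_that("cross-validation partitions trials and never leaks", {
  e <- toy_epochs(n_per_class = 25, seed = 5)
  ev <- crossval_evidence(e, train_times = c(0.02, 0.05), k_folds = 5, seed = 2)
  # every trial is scored exactly once, by the fold that held it out
  expect_equal(sort(unique(ev$folds)), 1:5)
  expect_equal(length(ev$folds), 50L)
  expect_true(all(table(ev$folds) %in% 9:11))   # 20% +/- 1 trial
  expect_true(all(is.finite(ev$values)))
  expect_error(crossval_evidence(subset_trials(e, 1:3),
                                 train_times = 0.02, k_folds = 5), "folds")

  # separable, noiseless classes: all cross-validated evidence positive
  sep <- toy_epochs(n_per_class = 20, sep = 4, noise_sd = 0.01, seed = 6)
  ev2 <- crossval_evidence(sep, train_times = 0.03, seed = 3)
  expect_true(all(ev2$values > 0))
})

test_that("accuracy counts positive-evidence trials", {
  ev <- toy_tensor(function(a, b) 1, train_times = c(0.1, 0.2),
                   test_times = c(0, 0.05), n_trials = 4)
  expect_true(all(accuracy_matrix(ev)$values == 1))
  ev$values[ , 1, 1] <- c(1, 1, -1, 1)
  expect_equal(accuracy_matrix(ev)$values[1, 1], 0.75)
})

test_that("evidence scales with the data but accuracy does not", {
  e <- toy_epochs(n_per_class = 15, seed = 7)
  ev1 <- crossval_evidence(e, train_times = 0.02, k_folds = 3, seed = 1)
  e2 <- e
  e2$data <- e$data * 3
  ev2 <- crossval_evidence(e2, train_times = 0.02, k_folds = 3, seed = 1)
  expect_true(all(ev1$values * ev2$values >= 0))  # same signs
  expect_equal(accuracy_matrix(ev1)$values, accuracy_matrix(ev2)$values)
})

test_that("shuffled labels give chance-level accuracy", {
  e <- toy_epochs(n_per_class = 100, sep = 2, noise_sd = 0.5, seed = 8)
  e$labels <- permute_labels(e$labels, seed = 9)
  ev <- crossval_evidence(e, train_times = c(0.02, 0.06), seed = 4)
  acc <- accuracy_matrix(ev)
  expect_gt(mean(acc$values), 0.4)
  expect_lt(mean(acc$values), 0.6)
})
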