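#' Balance class counts by random removal
#'
#' Removes trials drawn uniformly at random from the majority class only,
#' until both classes have equal counts. Applied per cross-validation fold to
#' the training split so the classifier sees no class prior.
#'
#' @param e an `epochs` object with both classes present.
#' @param seed integer seed for the removal draw.
#' @return An `epochs` object with equal class counts; retained trials keep
#'   their original order.
#' @export
balance_classes <- function(e, seed) {
  stopifnot(inherits(e, "epochs"))
  n0 <- sum(e$labels == 0L)
  n1 <- sum(e$labels == 1L)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present to balance")
  if (n0 == n1) return(e)
  maj <- if (n0 > n1) 0L else 1L
  excess <- abs(n0 - n1)
  set.seed(seed)
  drop_idx <- sample(which(e$labels == maj), excess)
  subset_trials(e, sort(setdiff(seq_len(n_trials(e)), drop_idx)))
}

#' Demean epochs over trials
#'
#' Subtracts, for every (sensor, time) pair, the mean over trials. This
#' removes global amplitude differences (e.g. between perception and imagery
#' epochs) while leaving the class-difference pattern untouched, forcing the
#' classifier to use relative changes in the multivariate signal.
#'
#' @param e an `epochs` object.
#' @return A demeaned `epochs` object.
#' @export
demean <- function(e) {
  stopifnot(inherits(e, "epochs"))
  mu <- colMeans(e$data)                       # sensors x time
  e$data <- e$data - rep(mu, each = n_trials(e))
  e
}

#' Train a shrinkage-LDA classifier at one time point
#'
#' Fits a linear discriminant on the sensor vector at the sample nearest
#' `train_time`: weights are the shrinkage-regularised pooled within-class
#' covariance inverse applied to the class-mean difference, with the bias
#' placing the decision boundary midway between the projected class means.
#' The shrinkage target is the identity scaled by the average diagonal
#' variance, blended in with weight `gamma` (default 0.05).
#'
#' @param e an `epochs` object with both classes present.
#' @param train_time training time point in seconds (snapped to the grid).
#' @param gamma shrinkage weight in `[0, 1]`.
#' @return A list of class `"lda_model"`: `weights`, `bias`, `train_time`
#'   (the grid time actually used), `gamma`, `fold`.
#' @export
train_lda <- function(e, train_time, gamma = 0.05) {
  stopifnot(inherits(e, "epochs"))
  if (gamma < 0 || gamma > 1) stop("'gamma' must be in [0, 1]")
  idx <- which.min(abs(e$times - train_time))
  x <- matrix(e$data[, , idx], n_trials(e), n_sensors(e))
  i0 <- e$labels == 0L
  i1 <- e$labels == 1L
  if (!any(i0) || !any(i1)) stop("both classes must be present at train_time")
  mu0 <- colMeans(x[i0, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  c0 <- stats::cov(x[i0, , drop = FALSE]) * (sum(i0) - 1L)
  c1 <- stats::cov(x[i1, , drop = FALSE]) * (sum(i1) - 1L)
  s <- (c0 + c1) / max(sum(i0) + sum(i1) - 2L, 1L)
  nu <- mean(diag(s))
  if (nu <= 0) nu <- 1                         # noise-free data: ridge target

  s_reg <- (1 - gamma) * s + gamma * nu * diag(n_sensors(e))
  w <- tryCatch(solve(s_reg, mu0 - mu1), error = function(err)
    stop("regularised covariance is numerically singular at train_time ",
         signif(e$times[idx], 4), "; increase gamma", call. = FALSE))
  structure(list(weights = as.numeric(w),
                 bias = -sum(w * (mu0 + mu1)) / 2,
                 train_time = e$times[idx], gamma = gamma, fold = NA_integer_),
            class = "lda_model")
}

#' Signed correct-class evidence of a classifier over a test window
#'
#' Computes the signed distance to the hyperplane at each test sample and
#' flips the sign for class-1 trials, so that increasingly positive values
#' always mean increasingly confident evidence for the trial's correct class.
#'
#' @param model an `"lda_model"`.
#' @param e an `epochs` object to evaluate on.
#' @param test_window length-2 numeric window in seconds.
#' @return trials x test-samples matrix of signed evidence, with the test
#'   times as the `"times"` attribute.
#' @export
evidence <- function(model, e, test_window = range(e$times)) {
  stopifnot(inherits(model, "lda_model"), inherits(e, "epochs"))
  idx <- window_indices(e$times, test_window)
  n <- n_trials(e)
  x <- matrix(aperm(e$data[, , idx, drop = FALSE], c(1, 3, 2)),
              n * length(idx), n_sensors(e))
  ev <- matrix(x %*% model$weights + model$bias, n, length(idx))
  flip <- e$labels == 1L
  ev[flip, ] <- -ev[flip, , drop = FALSE]
  attr(ev, "times") <- e$times[idx]
  ev
}

# stratified k-fold assignment: shuffle within class, deal into folds
make_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated evidence tensor
#'
#' For every requested training time point, trains a shrinkage-LDA model on
#' the training epochs of each cross-validation fold (classes balanced within
#' the fold's training split) and evaluates its signed correct-class evidence
#' on the paired test epochs of the held-out trials, so no trial is ever
#' scored by a model that saw it. Training and test epochs are paired
#' trial-by-trial (same labels and subjects); pass the same object twice for
#' a within-epoch analysis. Demeaning is applied to each epoch set as a
#' global preprocessing step before fold splitting.
#'
#' @param train an `epochs` object supplying the training data.
#' @param test an `epochs` object supplying the test data; defaults to
#'   `train`.
#' @param train_times numeric vector of training time points in seconds.
#' @param test_window length-2 test window in seconds.
#' @param k_folds number of folds (default 5: train on 80%, test on 20%).
#' @param gamma LDA shrinkage weight.
#' @param seed integer seed for fold assignment and balancing.
#' @param demean_data apply [demean()] to both epoch sets first.
#' @return A list of class `"evidence_tensor"`: `values` (trials x training
#'   times x test times), `train_times`, `test_times`, `folds`, `labels`,
#'   `subjects`, `fs`.
#' @export
crossval_evidence <- function(train, test = train, train_times,
                              test_window = range(test$times), k_folds = 5L,
                              gamma = 0.05, seed = 1L, demean_data = TRUE) {
  stopifnot(inherits(train, "epochs"), inherits(test, "epochs"))
  n <- n_trials(train)
  if (n_trials(test) != n || !identical(train$labels, test$labels))
    stop("'train' and 'test' must be paired trial-by-trial with equal labels")
  if (k_folds < 2L) stop("'k_folds' must be >= 2")
  if (n < k_folds) stop("fewer trials than folds")
  if (demean_data) {
    train <- demean(train)
    test <- demean(test)
  }
  tt_idx <- vapply(train_times, function(t) which.min(abs(train$times - t)),
                   integer(1))
  tt <- train$times[tt_idx]
  w_idx <- window_indices(test$times, test_window)
  fold <- make_folds(train$labels, k_folds, seed)

  values <- array(NA_real_, dim = c(n, length(tt), length(w_idx)))
  for (f in seq_len(k_folds)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    e_tr <- balance_classes(subset_trials(train, tr_idx),
                            seed = sub_seed(seed, f))
    wmat <- matrix(0, n_sensors(train), length(tt))
    bias <- numeric(length(tt))
    for (j in seq_along(tt)) {
      m <- train_lda(e_tr, tt[j], gamma)
      wmat[, j] <- m$weights
      bias[j] <- m$bias
    }
    x <- matrix(aperm(test$data[te_idx, , w_idx, drop = FALSE], c(1, 3, 2)),
                length(te_idx) * length(w_idx), n_sensors(test))
    proj <- x %*% wmat                           # (n_te * n_time) x n_tt
    for (j in seq_along(tt)) {
      evj <- matrix(proj[, j] + bias[j], length(te_idx), length(w_idx))
      flip <- test$labels[te_idx] == 1L
      evj[flip, ] <- -evj[flip, , drop = FALSE]
      values[te_idx, j, ] <- evj
    }
  }
  structure(list(values = values, train_times = tt,
                 test_times = test$times[w_idx], folds = fold,
                 labels = train$labels, subjects = train$subjects,
                 fs = test$fs),
            class = "evidence_tensor")
}

#' @export
print.evidence_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "evidence_tensor: %d trials x %d training times x %d test times\n",
    d[1], d[2], d[3]))
  invisible(x)
}

#' Temporal generalization accuracy matrix
#'
#' Entry (i, j) is the proportion of trials whose signed evidence at
#' (training time i, test time j) is positive, i.e. classified correctly.
#' Averaging over trials makes this matrix blind to between-trial timing
#' jitter, which is exactly the limitation the per-trial reactivation-time
#' analysis avoids.
#'
#' @param ev an `"evidence_tensor"`.
#' @return A list of class `"accuracy_matrix"`: `values` (training x test
#'   times, in `[0, 1]`), `train_times`, `test_times`, `n_trials`.
#' @export
accuracy_matrix <- function(ev) {
  stopifnot(inherits(ev, "evidence_tensor"))
  vals <- apply(ev$values > 0, c(2L, 3L), mean)
  structure(list(values = vals, train_times = ev$train_times,
                 test_times = ev$test_times, n_trials = dim(ev$values)[1L]),
            class = "accuracy_matrix")
}
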