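test_that("pattern generation is deterministic and informative", {
  cfg <- sim_config(seed = 1)
  p1 <- make_patterns(cfg)
  p2 <- make_patterns(cfg)
  expect_identical(p1$patterns, p2$patterns)
  expect_equal(dim(p1$stimulus_information), c(5L, 20L))
  # every pattern carries class information
  norms <- sqrt(rowSums(p1$stimulus_information^2))
  expect_true(all(norms > 0))
  expect_equal(p1$stimulus_information,
               matrix(p1$patterns[, , 1], 5, 20) -
                 matrix(p1$patterns[, , 2], 5, 20))
  expect_error(make_patterns(sim_config(n_sensors = 1)), "n_sensors")
})

test_that("AR(1) fit recovers known generators", {
  # white noise: no lag-1 structure
  set.seed(2)
  e <- epochs(array(rnorm(200 * 4 * 50), dim = c(200, 4, 50)),
              rep(0:1, each = 100), rep(1L, 200), (0:49) / 300, 300)
  fit <- fit_ar1(e)
  expect_lt(max(abs(fit$coefficients)), 0.05)
  expect_identical(fit$coefficients, fit_ar1(e)$coefficients)

  # diagonal 0.9 generator
  gen <- ar_model(0.9 * diag(4), diag(4))
  noise <- sample_noise(gen, n_trials = 60, n_samples = 120, seed = 3)
  e2 <- epochs(noise, rep(0:1, each = 30), rep(1L, 60), (0:119) / 300, 300)
  fit2 <- fit_ar1(e2)
  expect_true(all(abs(diag(fit2$coefficients) - 0.9) < 0.05))
})

test_that("AR(1) sampling matches its model", {
  # zero coefficients: white noise with the innovation covariance
  sigma <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  m0 <- ar_model(matrix(0, 2, 2), sigma)
  x <- sample_noise(m0, n_trials = 50, n_samples = 200, seed = 4)
  flat <- matrix(aperm(x, c(3, 1, 2)), 50 * 200, 2)
  expect_lt(max(abs(cov(flat) - sigma)), 0.05)

  # lag-1 autocorrelation of a 0.9 diagonal process
  m9 <- ar_model(0.9 * diag(2), diag(2))
  y <- sample_noise(m9, n_trials = 20, n_samples = 500, seed = 5)
  ac <- mean(vapply(1:20, function(i)
    cor(y[i, 1, -500], y[i, 1, -1]), numeric(1)))
  expect_lt(abs(ac - 0.9), 0.05)

  expect_identical(sample_noise(m9, 3, 10, seed = 6),
                   sample_noise(m9, 3, 10, seed = 6))
  expect_error(sample_noise(ar_model(1.1 * diag(2), diag(2)), 2, 10, 1),
               "stationary")
})

test_that("default noise model is stationary and 1/f-like", {
  m <- default_ar_model()
  expect_lt(max(Mod(eigen(m$coefficients, only.values = TRUE)$values)), 1)
  x <- sample_noise(m, n_trials = 8, n_samples = 512, seed = 7)
  fs <- 300
  pows <- rowMeans(vapply(1:8, function(i) {
    sp <- Mod(fft(x[i, 1, ]))^2
    sp[2:256]
  }, numeric(255)))
  freqs <- (1:255) / 512 * fs
  expect_gt(mean(pows[freqs < fs / 4]), mean(pows[freqs >= fs / 4]))
})

test_that("simulated datasets honour their configuration", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_class = 15, seed = 9)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim1$test$data, sim2$test$data)
  expect_equal(n_trials(sim1$train), 30L)
  expect_equal(length(sim1$test$times), 600L)
  expect_equal(sim1$test$fs, 300)

  # reversed schedule is the exact reversal of the same-order schedule
  s_same <- simulate_dataset(sim_config(n_subjects = 1, n_trials_per_class = 2,
                                        noise_scale = 0, seed = 9))
  s_rev <- simulate_dataset(sim_config(n_subjects = 1, n_trials_per_class = 2,
                                       noise_scale = 0, order = "reversed",
                                       seed = 9))
  expect_equal(s_rev$truth$pattern_times[, "start"],
               rev(s_same$truth$pattern_times[, "start"]))
  expect_equal(s_rev$truth$slope, -10)

  expect_error(simulate_dataset(sim_config(trial_length = 0.3)), "fit")
})

test_that("onset jitter follows the configured Gaussian", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_class = 100, onset_sd = 0.1,
                    noise_scale = 0, seed = 21)
  truth <- simulate_dataset(cfg)$truth
  on <- truth$trials$onset
  n <- length(on)
  expect_lt(abs(mean(on) - 0.8), 3 * 0.1 / sqrt(n))
  expect_lt(abs(sd(on) - 0.1), 3 * 0.1 / sqrt(2 * (n - 1)))
})

test_that("noise-free trials carry the placed sequence", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_class = 3, onset_sd = 0,
                    noise_scale = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  # all trials of a class identical
  expect_equal(sim$test$data[1, , ], sim$test$data[2, , ])
  # first-pattern activation peaks at the recorded onset (0.8 s)
  cfg2 <- sim_config(n_subjects = 1, n_trials_per_class = 10, onset_sd = 0.1,
                     noise_scale = 0, seed = 6)
  sim2 <- simulate_dataset(cfg2)
  pat <- sim2$truth$patterns[[1]]
  for (i in c(1, 5, 12)) {
    cl <- sim2$test$labels[i] + 1L
    proj <- as.numeric(pat$patterns[1, , cl] %*% sim2$test$data[i, , ])
    t_peak <- sim2$test$times[which.max(proj)]
    expect_lt(abs(t_peak - sim2$truth$trials$onset[i]), 1.5 / 300)
  }
})
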