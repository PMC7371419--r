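test_that("OLS order fit matches closed-form solutions", {
  tab <- toy_table(function(t) t)                      # identity relation
  fit <- suppressWarnings(fit_order_lm(tab))   # perfect fit warns
  expect_equal(fit$beta1, 1, tolerance = 1e-10)
  expect_equal(fit$beta0, 0, tolerance = 1e-10)

  # linear relation round-trip at the scale the method reports
  tab2 <- toy_table(function(t) 2.05 - 1.17 * t)
  fit2 <- suppressWarnings(fit_order_lm(tab2))
  expect_equal(fit2$beta1, -1.17, tolerance = 1e-8)
  expect_equal(fit2$beta0, 2.05, tolerance = 1e-8)

  # closed-form OLS oracle on noisy data
  tab3 <- toy_table(function(t) 1 - 3 * t, noise_sd = 0.2, seed = 4)
  fit3 <- fit_order_lm(tab3)
  x <- tab3$train_time
  y <- tab3$peak_time
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit3$beta1, b1, tolerance = 1e-10)
  expect_equal(fit3$beta0, mean(y) - b1 * mean(x), tolerance = 1e-10)

  const <- toy_table(function(t) t, train_times = 0.1)
  expect_error(fit_order_lm(const), "distinct")
})

test_that("slope magnitude recovers the generating slowdown", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_class = 30, onset_sd = 0.1,
                    noise_scale = 0.5, order = "reversed", seed = 41)
  sim <- simulate_dataset(cfg)
  rep <- run_reversal_analysis(sim$train, sim$test,
                               pipeline_config(seed = 42, boot = 0),
                               lmm = FALSE, shuffle = FALSE)
  ci <- rep$fit_lm$beta1 + c(-1.96, 1.96) * rep$fit_lm$se1
  expect_true(ci[1] <= -10 * 0.8 && -10 * 1.2 <= ci[2] ||
                abs(rep$fit_lm$beta1 + 10) < 2)
})

test_that("mixed models collapse to OLS without group variance", {
  tab <- toy_table(function(t) 1 + 0.5 * t, n_subjects = 4, n_trials = 6,
                   noise_sd = 0.05, seed = 5)
  sel <- fit_order_lmm(tab)
  lm_fit <- fit_order_lm(tab)
  for (f in sel$candidates)
    if (isTRUE(f$converged))
      expect_equal(f$beta1, lm_fit$beta1, tolerance = 1e-6)
  expect_true(sel$winner %in% seq_along(sel$candidates))
  expect_equal(sel$bic_table$structure[sel$winner],
               sel$candidates[[sel$winner]]$random_structure)
})

test_that("mixed models recover slopes under subject and trial intercepts", {
  slopes <- numeric(5)
  for (r in 1:5) {
    set.seed(r)
    shifts <- rnorm(6, sd = 0.3)
    tab <- toy_table(function(t) 1.5 - 1 * t, n_subjects = 6, n_trials = 8,
                     noise_sd = 0.05, subject_shift = shifts, seed = r + 50)
    tr_shift <- rnorm(max(tab$trial), sd = 0.15)   # trial-level intercepts
    tab$peak_time <- tab$peak_time + tr_shift[tab$trial]
    sel <- fit_order_lmm(tab)
    slopes[r] <- sel$candidates[[sel$winner]]$beta1
    if (r == 1) {
      # richer random structures beat plain OLS on the criterion
      bics <- sel$bic_table
      expect_lt(bics$bic[bics$structure == "subject_and_trial_intercept"],
                bics$bic[bics$structure == "none"])
      expect_true(all(c("subject_intercept", "trial_intercept") %in%
                        bics$structure))
    }
  }
  expect_lt(abs(mean(slopes) - (-1)), 0.1)
})

test_that("subject-level fit averages within subjects first", {
  shifts <- rep(0, 5)
  tab <- toy_table(function(t) 2 - 1.2 * t, n_subjects = 5, n_trials = 8,
                   noise_sd = 0.02, subject_shift = shifts, seed = 8)
  fit <- subject_level_fit(tab)
  pooled <- fit_order_lm(tab)
  expect_equal(fit$beta1, pooled$beta1, tolerance = 0.05)
  sel <- attr(fit, "selection")
  expect_equal(sel$candidates[[1]]$n,
               length(unique(tab$subject)) * length(unique(tab$train_time)))
  tab1 <- toy_table(function(t) t, n_subjects = 2)
  expect_error(subject_level_fit(tab1), "3 subjects")
})

test_that("shuffled controls destroy the order signal reproducibly", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_class = 25, onset_sd = 0.1,
                    noise_scale = 1, order = "reversed", seed = 51)
  sim <- simulate_dataset(cfg)
  settings <- list(train_window = c(0.07, 0.13), k_folds = 5, gamma = 0.05,
                   lowpass_hz = 30)
  true_tab <- reactime:::reactivation_table_pipeline(sim$train, sim$test,
                                                     settings, seed = 1)
  true_fit <- fit_order_lm(true_tab)
  null_fit <- shuffled_control(sim$train, sim$test, settings, seed = 2)
  expect_lt(abs(null_fit$beta1), abs(true_fit$beta1))
  null_fit2 <- shuffled_control(sim$train, sim$test, settings, seed = 2)
  expect_identical(null_fit$beta1, null_fit2$beta1)
  # permutation preserves the label multiset
  expect_identical(sort(permute_labels(sim$train$labels, 3)),
                   sort(sim$train$labels))
})
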