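test_that("EMD reconstructs its input and isolates oscillations", {
  fs <- 300
  t <- (0:120) / fs
  # constant input: nothing to extract
  dec0 <- emd(rep(3, 50))
  expect_equal(length(dec0$imfs), 0L)
  expect_equal(dec0$residual, rep(3, 50))

  s10 <- sin(2 * pi * 10 * t)
  dec1 <- emd(s10, times = t)
  expect_gte(length(dec1$imfs), 1L)
  expect_gt(cor(dec1$imfs[[1]], s10), 0.99)

  # two-tone separation: fast IMF first
  mix <- sin(2 * pi * 10 * t) + sin(2 * pi * 1 * t)
  dec2 <- emd(mix, times = t)
  expect_gt(cor(dec2$imfs[[1]], sin(2 * pi * 10 * t)), 0.9)

  # exact reconstruction on assorted signals
  set.seed(1)
  for (k in 1:5) {
    x <- cumsum(rnorm(90)) + sin(2 * pi * 8 * (1:90) / fs)
    dec <- emd(x)
    recon <- Reduce(`+`, dec$imfs, dec$residual)
    expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-6)
  }
})

test_that("IMF selection targets the expected extrema count", {
  fs <- 300
  t <- (0:120) / fs
  dec <- emd(sin(2 * pi * 10 * t), times = t)
  sel <- select_imf(dec, 8)
  expect_equal(sel$count, 8L)

  fake <- structure(list(imfs = list(sin(2 * pi * 15 * t),   # 12 extrema
                                     sin(2 * pi * 10 * t),   # 8 extrema
                                     sin(2 * pi * 2.5 * t)), # 2 extrema
                         residual = 0 * t, times = t), class = "imf_set")
  expect_equal(select_imf(fake, 8)$index, 2L)
  tie <- structure(list(imfs = list(sin(2 * pi * 8.75 * t),  # 7 extrema
                                    sin(2 * pi * 11.25 * t)),# 9 extrema
                        residual = 0 * t, times = t), class = "imf_set")
  expect_equal(select_imf(tie, 8)$index, 1L)                 # tie: faster IMF
  empty <- structure(list(imfs = list(), residual = t, times = t),
                     class = "imf_set")
  expect_error(select_imf(empty), "empty")
})

test_that("phases segment between extrema with alternating directions", {
  fs <- 300
  t <- (0:120) / fs
  s <- sin(2 * pi * 10 * t)
  sel <- select_imf(emd(s, times = t), 8)
  ph <- segment_phases(sel$imf, sel$extrema_idx, t)
  expect_equal(nrow(ph), 7L)                    # 8 extrema -> 7 phases
  expect_true(all(ph$direction[-1] != ph$direction[-7]))
  expect_true(all(diff(ph$t_start) > 0))
  expect_error(segment_phases(s, 5L, t), "2 extrema")
})

test_that("fixed-frequency segmentation tiles the window", {
  ph <- fixed_freq_phases(10, c(0, 0.4))
  expect_equal(nrow(ph), 8L)
  expect_equal(unique(round(ph$t_end - ph$t_start, 9)), 0.05)
  expect_equal(sum(ph$direction == "increasing"), 4L)
  expect_equal(nrow(fixed_freq_phases(5, c(0, 0.4))), 4L)
  expect_equal(nrow(fixed_freq_phases(10, c(0, 0.05))), 1L)
  # floor(2 f |W|) phases when integral
  expect_equal(nrow(fixed_freq_phases(25, c(0.1, 0.5))), 20L)
  expect_error(fixed_freq_phases(1, c(0, 0.1)), "shorter")
})

test_that("hypothesis matrices encode direction agreement", {
  same <- structure(data.frame(t_start = c(0, 1), t_end = c(1, 2),
                               direction = "increasing"),
                    class = c("phase_set", "data.frame"))
  # build via constructor for the alternating case
  alt <- fixed_freq_phases(10, c(0, 0.4))
  h <- hypothesis_matrix(alt, alt)
  expect_true(all(diag(h) == 1))
  expect_equal(h, outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0,
                                                        1, -1)))
  one <- fixed_freq_phases(10, c(0, 0.05))
  expect_equal(hypothesis_matrix(one, one), matrix(1, 1, 1))
  expect_true(all(outer(same$direction, same$direction, `==`)))
})

test_that("phase-pair slopes recover constructed structure", {
  fs <- 300
  tt <- seq(0, 0.4, by = 1 / fs)
  alt <- fixed_freq_phases(10, c(0, 0.4), phase0 = "increasing")
  # evidence whose peak, within any test phase, alternates direction with
  # the parity of the train phase: a checkerboard generator
  phase_of <- function(x) pmin(floor(x / 0.05), 7)
  f <- function(a, b) {
    pa <- phase_of(a); pb <- phase_of(b)
    ra <- (a - pa * 0.05) / 0.05
    rb <- (b - pb * 0.05) / 0.05
    target <- ifelse((pa + pb) %% 2 == 0, ra, 1 - ra)
    -(rb - target)^2
  }
  ev <- toy_tensor(f, tt, tt, n_trials = 6, fs = fs)
  sl <- phase_slopes(ev, alt, alt)
  h <- hypothesis_matrix(alt, alt)
  expect_true(all(sign(sl$slopes) == h))
  expect_true(all(abs(abs(sl$slopes) - 1) < 0.35))

  # peak at the train time's within-phase position: all slopes positive
  f_same <- function(a, b) {
    ra <- (a - phase_of(a) * 0.05) / 0.05
    rb <- (b - phase_of(b) * 0.05) / 0.05
    -(rb - ra)^2
  }
  ev2 <- toy_tensor(f_same, tt, tt, n_trials = 4, fs = fs)
  sl2 <- phase_slopes(ev2, alt, alt)
  expect_true(all(sl2$slopes > 0))

  # constant peaks: zero slopes
  ev3 <- toy_tensor(function(a, b) -(b - 0.21)^2, tt, tt, n_trials = 4,
                    fs = fs)
  sl3 <- phase_slopes(ev3, alt, alt)
  expect_true(all(abs(sl3$slopes) < 1e-10))
})

test_that("the Recurrence Index is the hypothesis-slope dot product", {
  h2 <- matrix(c(1, -1, -1, 1), 2)
  ri <- recurrence_index(matrix(c(0.5, -0.1, -0.2, 0.3), 2), h2, n_boot = 0)
  expect_equal(ri$ri, 1.1)
  h8 <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  expect_equal(recurrence_index(h8, h8, n_boot = 0)$ri, 64)
  expect_equal(recurrence_index(matrix(0, 3, 3), matrix(1, 3, 3),
                                n_boot = 0)$ri, 0)
  # bilinearity in the slope matrix
  set.seed(2)
  s1 <- matrix(rnorm(16), 4)
  s2 <- matrix(rnorm(16), 4)
  h4 <- matrix(sample(c(-1, 1), 16, TRUE), 4)
  ri_lin <- recurrence_index(2 * s1 + 3 * s2, h4, n_boot = 0)$ri
  expect_equal(ri_lin, 2 * recurrence_index(s1, h4, n_boot = 0)$ri +
                 3 * recurrence_index(s2, h4, n_boot = 0)$ri,
               tolerance = 1e-10)
  expect_error(recurrence_index(s1, h2), "shape")
})

test_that("near-diagonal RI separates local from distant recurrence", {
  h <- outer(1:5, 1:5, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  s_band <- h * (abs(row(h) - col(h)) <= 1)
  nb <- neighbor_ri(s_band, h, n_boot = 0)
  expect_gt(nb$near, 0)
  expect_equal(nb$far, 0)
  nb2 <- neighbor_ri(h, h, n_boot = 0)
  expect_equal(nb2$near, nb2$far)
  nb3 <- neighbor_ri(matrix(0, 5, 5), h, n_boot = 0)
  expect_equal(c(nb3$near, nb3$far), c(0, 0))
  expect_error(neighbor_ri(matrix(0, 2, 2), matrix(1, 2, 2)), "3 x 3")
})
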