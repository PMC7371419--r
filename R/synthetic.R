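#' Simulation configuration
#'
#' Bundles the generative settings for [simulate_dataset()]: a sequence of
#' `n_patterns` sensor patterns activated over `train_seq_duration` seconds
#' forms the "perception" training data; the same patterns, slowed down by
#' `slowdown` and placed at a jittered per-trial onset, form the "imagery"
#' test data; multivariate AR(1) noise is added to both. Defaults follow the
#' validation simulation the method was developed with: 5 patterns over 20
#' sensors, a 60 ms training sequence at 300 Hz, 100 trials per class, test
#' trials of 2 s, onsets drawn from N(0.8 s, 0.1 or 0.5 s), slowdown 10, and
#' 10 subjects.
#'
#' @param n_patterns number of sequentially activated sensor patterns.
#' @param n_sensors number of sensors (abstract channels).
#' @param fs sampling rate in Hz.
#' @param train_seq_duration training-sequence duration in seconds.
#' @param n_trials_per_class trials per class, per subject, per epoch set.
#' @param onset_mean,onset_sd Gaussian onset distribution of the slowed test
#'   sequence, in seconds.
#' @param slowdown temporal slowing factor of the test sequence (>= 1).
#' @param trial_length test-trial length in seconds.
#' @param order `"same"` or `"reversed"`: order of the test sequence relative
#'   to training.
#' @param n_subjects number of simulated subjects.
#' @param noise_scale stationary standard deviation of the ongoing AR(1)
#'   noise relative to the unit-norm activation patterns; 0 disables noise.
#'   The default (6) is calibrated so cross-validated single-trial peak
#'   decoding accuracy lands in the 0.55--0.65 range typical of MEG category
#'   decoding, which is the regime where the accuracy-matrix/peak-timing
#'   dissociation the generator exists to demonstrate actually occurs.
#' @param train_seq_start start of the training sequence on the training time
#'   axis, seconds (the canonical feed-forward window begins at 70 ms).
#' @param seed integer master seed.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_patterns = 5L, n_sensors = 20L, fs = 300,
                       train_seq_duration = 0.060, n_trials_per_class = 100L,
                       onset_mean = 0.8, onset_sd = 0.1, slowdown = 10,
                       trial_length = 2.0, order = c("same", "reversed"),
                       n_subjects = 10L, noise_scale = 6,
                       train_seq_start = 0.070, seed = 1L) {
  order <- match.arg(order)
  cfg <- list(n_patterns = as.integer(n_patterns),
              n_sensors = as.integer(n_sensors), fs = fs,
              train_seq_duration = train_seq_duration,
              n_trials_per_class = as.integer(n_trials_per_class),
              onset_mean = onset_mean, onset_sd = onset_sd,
              slowdown = slowdown, trial_length = trial_length, order = order,
              n_subjects = as.integer(n_subjects), noise_scale = noise_scale,
              train_seq_start = train_seq_start, seed = as.integer(seed))
  counts <- c("n_patterns", "n_sensors", "n_trials_per_class", "n_subjects")
  for (f in counts) if (cfg[[f]] < 1L) stop("'", f, "' must be >= 1")
  if (cfg$fs <= 0) stop("'fs' must be positive")
  if (cfg$onset_sd < 0) stop("'onset_sd' must be >= 0")
  if (cfg$slowdown < 1) stop("'slowdown' must be >= 1")
  if (cfg$noise_scale < 0) stop("'noise_scale' must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# derive a reproducible sub-seed; keeps values within 32-bit integer range
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + k * 7919) %% 2147483629)
}

# raised-cosine (Hann) activation envelopes: pattern centres evenly spaced
# across the sequence, each window overlapping its neighbours by 50%
pattern_envelopes <- function(times, centers, halfwidth) {
  env <- matrix(0, length(centers), length(times))
  for (k in seq_along(centers)) {
    d <- times - centers[k]
    inside <- abs(d) < halfwidth
    env[k, inside] <- 0.5 * (1 + cos(pi * d[inside] / halfwidth))
  }
  env
}

# centres of the n pattern windows over a sequence of given duration;
# the first pattern peaks at the sequence onset, the last at its end
pattern_centers <- function(n, duration) {
  if (n == 1L) return(duration / 2)
  (seq_len(n) - 1) / (n - 1) * duration
}

#' Pseudo-random sensor activation patterns
#'
#' Draws `n_patterns` independent sensor patterns for each of the two
#' stimulus classes, entries i.i.d. standard normal. Stimulus information is
#' the class difference: what a linear classifier can pick up.
#'
#' @param config a [sim_config()].
#' @return A list of class `"pattern_set"`: `patterns` (n_patterns x
#'   n_sensors x 2) and `stimulus_information` (n_patterns x n_sensors,
#'   class-0 pattern minus class-1 pattern).
#' @export
make_patterns <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_sensors < 2L) stop("'n_sensors' must be >= 2")
  set.seed(config$seed)
  pat <- array(stats::rnorm(config$n_patterns * config$n_sensors * 2),
               dim = c(config$n_patterns, config$n_sensors, 2))
  # unit-norm activation patterns: noise_scale is then interpretable as the
  # ongoing-noise SD relative to the pattern amplitude
  for (k in seq_len(config$n_patterns)) for (cl in 1:2)
    pat[k, , cl] <- pat[k, , cl] / sqrt(sum(pat[k, , cl]^2))
  info <- matrix(pat[, , 1], config$n_patterns, config$n_sensors) -
    matrix(pat[, , 2], config$n_patterns, config$n_sensors)
  structure(list(patterns = pat, stimulus_information = info),
            class = "pattern_set")
}

#' Multivariate AR(1) noise model
#'
#' @param coefficients n_sensors x n_sensors lag-1 coefficient matrix.
#' @param innovation_cov symmetric positive semi-definite innovation
#'   covariance.
#' @param mean per-sensor offset.
#' @return A list of class `"ar_model"`.
#' @export
ar_model <- function(coefficients, innovation_cov,
                     mean = rep(0, nrow(coefficients))) {
  coefficients <- as.matrix(coefficients)
  innovation_cov <- as.matrix(innovation_cov)
  p <- nrow(coefficients)
  if (ncol(coefficients) != p) stop("'coefficients' must be square")
  if (!all(dim(innovation_cov) == p))
    stop("'innovation_cov' dimensions must match 'coefficients'")
  if (max(abs(innovation_cov - t(innovation_cov))) > 1e-8)
    stop("'innovation_cov' must be symmetric")
  structure(list(coefficients = coefficients,
                 innovation_cov = (innovation_cov + t(innovation_cov)) / 2,
                 mean = mean),
            class = "ar_model")
}

spectral_radius <- function(a) max(Mod(eigen(a, only.values = TRUE)$values))

#' Default synthetic AR(1) noise model
#'
#' A synthetic stand-in for ongoing recordings: spatially smooth lag-1
#' coefficients with spectral radius `rho` and a spatially correlated
#' innovation covariance. The strong positive diagonal gives the sampled
#' noise a 1/f-like power spectrum. For 20 sensors the model is read from the
#' packaged synthetic fixture; other sizes are constructed analytically by
#' the same recipe.
#'
#' @param n_sensors number of channels.
#' @param rho target spectral radius of the coefficient matrix.
#' @return An `"ar_model"`.
#' @export
default_ar_model <- function(n_sensors = 20L, rho = 0.95) {
  fixture <- system.file("extdata", "ar1_synthetic_coefficients.tsv",
                         package = "reactime")
  if (n_sensors == 20L && rho == 0.95 && nzchar(fixture)) {
    a <- as.matrix(utils::read.table(fixture, sep = "\t"))
    s <- as.matrix(utils::read.table(
      system.file("extdata", "ar1_synthetic_innovation_cov.tsv",
                  package = "reactime"), sep = "\t"))
    dimnames(a) <- dimnames(s) <- NULL
    return(ar_model(a, s))
  }
  synthetic_ar_model(n_sensors, rho)
}

#' @rdname default_ar_model
#' @export
synthetic_ar_model <- function(n_sensors = 20L, rho = 0.95) {
  idx <- seq_len(n_sensors)
  k <- exp(-abs(outer(idx, idx, "-")) / 2)
  a <- rho * k / spectral_radius(k)
  sigma <- exp(-abs(outer(idx, idx, "-")) / 4)
  ar_model(a, sigma)
}

#' Stationary covariance of an AR(1) model
#'
#' Solves the discrete Lyapunov equation `P = A P A' + Sigma`.
#'
#' @param model an `"ar_model"` with spectral radius < 1.
#' @return n_sensors x n_sensors stationary covariance matrix.
#' @export
stationary_cov <- function(model) {
  a <- model$coefficients
  p <- nrow(a)
  if (spectral_radius(a) >= 1)
    stop("AR(1) model is not stationary (spectral radius >= 1)")
  vecp <- solve(diag(p * p) - kronecker(a, a), as.vector(model$innovation_cov))
  matrix(vecp, p, p)
}

#' Fit a multivariate AR(1) model to epoched data
#'
#' Least-squares lag-1 regression of each sample on the previous sample,
#' pooled across trials (trial boundaries are respected: no lagged pair spans
#' two trials). Data are centred per sensor before fitting; the centring is
#' recorded as the model mean.
#'
#' @param e an `epochs` object with at least 2 time samples.
#' @return An `"ar_model"` with estimated coefficients, innovation covariance
#'   and mean.
#' @export
fit_ar1 <- function(e) {
  stopifnot(inherits(e, "epochs"))
  d <- dim(e$data)
  if (d[3L] < 2L) stop("need at least 2 time samples to fit an AR(1) model")
  mu <- apply(e$data, 2L, mean)
  n_pair <- d[1L] * (d[3L] - 1L)
  x0 <- matrix(0, n_pair, d[2L])
  x1 <- matrix(0, n_pair, d[2L])
  row <- 1L
  for (i in seq_len(d[1L])) {
    tr <- t(e$data[i, , ]) - rep(mu, each = d[3L])
    idx <- row:(row + d[3L] - 2L)
    x0[idx, ] <- tr[-d[3L], , drop = FALSE]
    x1[idx, ] <- tr[-1L, , drop = FALSE]
    row <- row + d[3L] - 1L
  }
  xtx <- crossprod(x0)
  if (rcond(xtx) < 1e-12)
    stop("regressor covariance is numerically singular; consider adding a ",
         "ridge penalty or more data")
  a <- t(solve(xtx, crossprod(x0, x1)))
  resid <- x1 - x0 %*% t(a)
  sigma <- crossprod(resid) / (n_pair - 1L)
  ar_model(a, (sigma + t(sigma)) / 2, mean = mu)
}

#' Sample trial-wise noise from an AR(1) model
#'
#' Each trial is an independent realisation; a burn-in is discarded so the
#' process is approximately stationary from the first retained sample.
#'
#' @param model a stationary `"ar_model"`.
#' @param n_trials,n_samples output dimensions.
#' @param seed integer seed.
#' @param burn_in samples discarded at the start of each realisation.
#' @return numeric array, n_trials x n_sensors x n_samples.
#' @export
sample_noise <- function(model, n_trials, n_samples, seed, burn_in = 200L) {
  stopifnot(inherits(model, "ar_model"))
  a <- model$coefficients
  p <- nrow(a)
  if (spectral_radius(a) >= 1)
    stop("cannot sample: AR(1) model is not stationary (spectral radius >= 1)")
  eg <- eigen(model$innovation_cov, symmetric = TRUE)
  l <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), p)
  set.seed(seed)
  x <- matrix(0, p, n_trials)
  out <- array(0, dim = c(n_trials, p, n_samples))
  for (t in seq_len(burn_in + n_samples)) {
    x <- a %*% x + l %*% matrix(stats::rnorm(p * n_trials), p, n_trials)
    if (t > burn_in) out[, , t - burn_in] <- t(x)
  }
  out + rep(model$mean, each = n_trials)
}

# scale an AR model's innovations so the stationary per-sensor SD averages
# to `target_sd`
scale_ar_model <- function(model, target_sd) {
  p0 <- stationary_cov(model)
  s <- target_sd / sqrt(mean(diag(p0)))
  ar_model(model$coefficients, model$innovation_cov * s^2, model$mean)
}

# sensors x time signal for one class: envelope-weighted sum of patterns
class_signal <- function(pattern_set, class, env) {
  pk <- matrix(pattern_set$patterns[, , class],
               dim(pattern_set$patterns)[1L], dim(pattern_set$patterns)[2L])
  t(pk) %*% env
}

#' Simulate a ground-truth dataset
#'
#' Generates, per subject, a training epoch set in which `n_patterns` sensor
#' patterns activate in a partially overlapping sequence (raised-cosine
#' windows, 50% neighbour overlap, the first pattern peaking at the sequence
#' onset and the last at its end), and a test epoch set containing the same
#' patterns slowed down by `slowdown`, in the same or reversed order, at a
#' per-trial onset drawn from N(onset_mean, onset_sd); trials whose jittered
#' sequence runs past a trial edge are truncated by the trial window, which
#' keeps the onset law exactly Gaussian. Multivariate AR(1) noise is added
#' to both sets. The injected truth (onsets, order, per-pattern activation
#' intervals) is returned for recovery tests.
#'
#' @param config a [sim_config()].
#' @param ar an optional `"ar_model"` noise source; defaults to
#'   [default_ar_model()] rescaled to `config$noise_scale`.
#' @return A list with elements `train` (epochs), `test` (epochs) and `truth`
#'   (class `"ground_truth"`: data.frame `trials` with subject, trial, label,
#'   onset; `order`; `pattern_times` matrix of onset-relative activation
#'   intervals; `slope` = the generating train-to-test time slope).
#' @export
simulate_dataset <- function(config, ar = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  n_pat <- config$n_patterns
  d <- config$train_seq_duration
  centers_rel <- pattern_centers(n_pat, d)
  hw <- if (n_pat == 1L) d / 2 else d / (n_pat - 1)

  # the slowed sequence must fit inside the trial when placed at its mean
  # onset; individual jittered trials may run off the edges and are then
  # simply truncated by the trial window, preserving the Gaussian onset law
  m_test <- config$slowdown * hw
  if (config$slowdown * d + 2 * m_test > config$trial_length)
    stop("slowed sequence (", config$slowdown * d + 2 * m_test,
         " s support) does not fit inside a ", config$trial_length, " s trial")

  if (config$noise_scale > 0) {
    if (is.null(ar)) ar <- default_ar_model(config$n_sensors)
    ar <- scale_ar_model(ar, config$noise_scale)
  }

  # training time axis: sequence in [train_seq_start, train_seq_start + d],
  # plus envelope support and 20 ms of pure-noise margin on either side
  margin <- 0.020
  i0 <- floor((config$train_seq_start - hw - margin) * fs)
  i1 <- ceiling((config$train_seq_start + d + hw + margin) * fs)
  t_train <- (i0:i1) / fs
  t_test <- (0:(round(config$trial_length * fs) - 1L)) / fs

  centers_train <- config$train_seq_start + centers_rel
  env_train <- pattern_envelopes(t_train, centers_train, hw)

  npc <- config$n_trials_per_class
  n <- 2L * npc
  labels <- rep(0:1, each = npc)

  sched <- if (config$order == "reversed") rev(centers_rel) else centers_rel
  pattern_times <- cbind(start = config$slowdown * (sched - hw),
                         end = config$slowdown * (sched + hw))

  train_list <- vector("list", config$n_subjects)
  test_list <- vector("list", config$n_subjects)
  truth_rows <- vector("list", config$n_subjects)
  patterns <- vector("list", config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    cfg_s <- config
    cfg_s$seed <- sub_seed(config$seed, 11L * s)
    ps <- make_patterns(cfg_s)
    patterns[[s]] <- ps

    sig_train <- list(class_signal(ps, 1L, env_train),
                      class_signal(ps, 2L, env_train))
    dat_train <- array(0, dim = c(n, config$n_sensors, length(t_train)))
    for (i in seq_len(n)) dat_train[i, , ] <- sig_train[[labels[i] + 1L]]
    if (config$noise_scale > 0)
      dat_train <- dat_train +
        sample_noise(ar, n, length(t_train), sub_seed(config$seed, 11L * s + 1L))

    set.seed(sub_seed(config$seed, 11L * s + 2L))
    onsets <- stats::rnorm(n, config$onset_mean, config$onset_sd)

    dat_test <- array(0, dim = c(n, config$n_sensors, length(t_test)))
    for (i in seq_len(n)) {
      env_i <- pattern_envelopes(t_test, onsets[i] + config$slowdown * sched, m_test)
      dat_test[i, , ] <- class_signal(ps, labels[i] + 1L, env_i)
    }
    if (config$noise_scale > 0)
      dat_test <- dat_test +
        sample_noise(ar, n, length(t_test), sub_seed(config$seed, 11L * s + 3L))

    subj <- rep(s, n)
    train_list[[s]] <- list(dat_train, labels, subj)
    test_list[[s]] <- list(dat_test, labels, subj)
    truth_rows[[s]] <- data.frame(subject = s, trial = seq_len(n),
                                  label = labels, onset = onsets)
  }

  bind_ep <- function(lst, times) {
    dat <- do.call(abind1, lapply(lst, `[[`, 1L))
    epochs(dat, unlist(lapply(lst, `[[`, 2L)),
           unlist(lapply(lst, `[[`, 3L)), times, fs)
  }
  train <- bind_ep(train_list, t_train)
  test <- bind_ep(test_list, t_test)
  truth_df <- do.call(rbind, truth_rows)
  test$onsets <- truth_df$onset

  truth <- structure(
    list(trials = truth_df, order = config$order,
         pattern_times = pattern_times,
         slope = if (config$order == "reversed") -config$slowdown else config$slowdown,
         train_seq_window = c(config$train_seq_start, config$train_seq_start + d),
         patterns = patterns),
    class = "ground_truth")
  list(train = train, test = test, truth = truth)
}

# bind 3-d arrays along the first (trial) dimension
abind1 <- function(...) {
  arrs <- list(...)
  if (length(arrs) == 1L) return(arrs[[1L]])
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  out <- array(0, dim = c(n, d[2L], d[3L]))
  at <- 1L
  for (a in arrs) {
    k <- dim(a)[1L]
    out[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  out
}

#' Simulate a dataset with phase-alternating activation order
#'
#' Builds a single epoch set (used as both training and testing material, as
#' in a within-perception analysis) in which the full pattern sequence plays
#' once per half-period of `alternation_hz`, with the playback direction
#' reversing every phase when `alternating = TRUE` (and constant otherwise).
#' This is the recurrence fixture: classifiers trained in one phase should
#' reactivate in the same order within same-direction test phases and in
#' reversed order within opposite-direction phases.
#'
#' @param n_subjects,n_trials_per_class,n_patterns,n_sensors,fs,noise_scale
#'   as in [sim_config()].
#' @param window analysed time window in seconds.
#' @param alternation_hz alternation frequency; each phase lasts half a
#'   period.
#' @param alternating if `FALSE`, every phase plays the sequence forward (a
#'   negative control with no recurrence).
#' @param seed integer master seed.
#' @return A list with `data` (epochs) and `phases` (the generating
#'   `phase_set`).
#' @export
simulate_recurrence_dataset <- function(n_subjects = 5L,
                                        n_trials_per_class = 100L,
                                        n_patterns = 5L, n_sensors = 20L,
                                        fs = 300, window = c(0, 0.4),
                                        alternation_hz = 10,
                                        alternating = TRUE,
                                        noise_scale = 6, seed = 1L) {
  phase_len <- 1 / (2 * alternation_hz)
  n_phases <- floor(diff(window) * 2 * alternation_hz + 1e-9)
  if (n_phases < 1L) stop("window shorter than half an alternation period")
  hw <- phase_len / n_patterns
  within <- (seq_len(n_patterns) - 0.5) / n_patterns * phase_len

  margin <- 0.020
  i0 <- floor((window[1] - margin) * fs)
  i1 <- ceiling((window[2] + margin) * fs)
  times <- (i0:i1) / fs

  centers <- numeric(0)
  pattern_id <- integer(0)
  for (p in seq_len(n_phases)) {
    fwd <- !alternating || (p %% 2L == 1L)
    ord <- if (fwd) seq_len(n_patterns) else rev(seq_len(n_patterns))
    centers <- c(centers, window[1] + (p - 1) * phase_len + within)
    pattern_id <- c(pattern_id, ord)
  }

  npc <- n_trials_per_class
  n <- 2L * npc
  labels <- rep(0:1, each = npc)
  ar <- if (noise_scale > 0)
    scale_ar_model(default_ar_model(n_sensors), noise_scale) else NULL

  env <- pattern_envelopes(times, centers, hw)
  sets <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg_s <- sim_config(n_patterns = n_patterns, n_sensors = n_sensors,
                        seed = sub_seed(seed, 13L * s))
    ps <- make_patterns(cfg_s)
    sig <- lapply(1:2, function(cl) {
      pk <- matrix(ps$patterns[pattern_id, , cl], length(pattern_id), n_sensors)
      t(pk) %*% env
    })
    dat <- array(0, dim = c(n, n_sensors, length(times)))
    for (i in seq_len(n)) dat[i, , ] <- sig[[labels[i] + 1L]]
    if (!is.null(ar))
      dat <- dat + sample_noise(ar, n, length(times), sub_seed(seed, 13L * s + 1L))
    sets[[s]] <- dat
  }
  dat <- do.call(abind1, sets)
  e <- epochs(dat, rep(labels, n_subjects),
              rep(seq_len(n_subjects), each = n), times, fs)
  phases <- fixed_freq_phases(alternation_hz, window, phase0 = "increasing")
  list(data = e, phases = phases)
}
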