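# shared in-code fixtures: everything is generated at test time

# small epochs object with a constant class-difference pattern
toy_epochs <- function(n_per_class = 20, n_sensors = 4, n_time = 30,
                       fs = 300, sep = 1, noise_sd = 0.1, seed = 1,
                       subjects = NULL) {
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- rep(0:1, each = n_per_class)
  pattern <- seq_len(n_sensors) / n_sensors
  dat <- array(rnorm(n * n_sensors * n_time, sd = noise_sd),
               dim = c(n, n_sensors, n_time))
  for (i in seq_len(n)) {
    sgn <- if (labels[i] == 0L) 1 else -1
    dat[i, , ] <- dat[i, , ] + sgn * sep * pattern / 2
  }
  epochs(dat, labels, subjects %||% rep(1L, n), (0:(n_time - 1L)) / fs, fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built evidence tensor: values[trial, train, test] from a function
# f(train_time, test_time) plus optional per-trial noise
toy_tensor <- function(f, train_times, test_times, n_trials = 8, fs = 300,
                       noise_sd = 0, seed = 1, subjects = NULL) {
  set.seed(seed)
  base <- outer(train_times, test_times, Vectorize(f))
  values <- array(0, dim = c(n_trials, length(train_times), length(test_times)))
  for (i in seq_len(n_trials))
    values[i, , ] <- base + rnorm(length(base), sd = noise_sd)
  structure(list(values = values, train_times = train_times,
                 test_times = test_times,
                 folds = rep_len(1:2, n_trials),
                 labels = rep_len(0:1, n_trials),
                 subjects = subjects %||% rep(1L, n_trials), fs = fs),
            class = "evidence_tensor")
}

# reactivation table with peak_time = g(train_time) + noise
toy_table <- function(g, train_times = seq(0.07, 0.13, by = 1 / 300),
                      n_subjects = 1, n_trials = 10, noise_sd = 0,
                      subject_shift = NULL, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(trial = seq_len(n_trials), subject = seq_len(n_subjects),
                      train_time = train_times)
  shift <- if (is.null(subject_shift)) rep(0, n_subjects) else subject_shift
  rows$peak_time <- g(rows$train_time) + shift[rows$subject] +
    rnorm(nrow(rows), sd = noise_sd)
  rows$trial <- rows$trial + (rows$subject - 1L) * n_trials
  structure(rows[c("subject", "trial", "train_time", "peak_time")],
            train_times = train_times,
            class = c("reactivation_table", "data.frame"))
}
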