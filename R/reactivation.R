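#' Zero-phase low-pass filtering
#'
#' Removes high-frequency noise from evidence traces before peak extraction.
#' A 4th-order Butterworth low-pass is applied with zero phase (forward and
#' backward, realised as the squared magnitude response in the frequency
#' domain on an odd-reflection-padded signal), so peaks are not displaced by
#' group delay. DC gain is exactly 1.
#'
#' @param x numeric vector, or matrix with one trace per row.
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param fs sampling rate in Hz.
#' @param order filter order (of the underlying one-pass filter).
#' @return Filtered traces, same shape as `x`.
#' @export
lowpass <- function(x, cutoff, fs, order = 4L) {
  if (cutoff >= fs / 2) stop("'cutoff' must be below the Nyquist frequency")
  if (cutoff <= 0) stop("'cutoff' must be positive")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, 1L) else as.matrix(x)
  n <- ncol(m)
  np <- min(n - 1L, 3L * ceiling(fs / cutoff))
  if (np > 0L) {
    left <- 2 * m[, 1L] - m[, (np + 1L):2L, drop = FALSE]
    right <- 2 * m[, n] - m[, (n - 1L):(n - np), drop = FALSE]
    m <- cbind(left, m, right)
  }
  nn <- ncol(m)
  f <- (seq_len(nn) - 1L) / nn * fs
  f <- pmin(f, fs - f)
  h <- 1 / (1 + (f / cutoff)^(2 * order))      # |H|^2 of the Butterworth
  y <- Re(t(stats::mvfft(stats::mvfft(t(m)) * h, inverse = TRUE))) / nn
  if (np > 0L) y <- y[, (np + 1L):(np + n), drop = FALSE]
  if (vec) drop(y) else y
}

#' Time of peak evidence within a window
#'
#' The moment a perception model "became active": the test time at which the
#' signed correct-class evidence is maximal inside the search window. Ties
#' are broken toward the earliest sample.
#'
#' @param trace numeric evidence trace.
#' @param times sample times in seconds, same length as `trace`.
#' @param window length-2 search window in seconds.
#' @return Peak time in seconds.
#' @export
peak_time <- function(trace, times, window = range(times)) {
  idx <- window_indices(times, window)
  v <- trace[idx]
  if (all(is.na(v))) stop("evidence trace is all-NA inside the window")
  times[idx][which.max(v)]
}

#' Per-trial reactivation-time table
#'
#' For every (trial, training time) pair, finds the test time of peak signed
#' evidence within `window`, optionally after zero-phase low-pass filtering
#' of each trial's evidence trace. This trial-resolved timing estimate is the
#' pipeline's central statistic: unlike the trial-averaged accuracy matrix,
#' it survives between-trial onset jitter.
#'
#' @param ev an `"evidence_tensor"`.
#' @param window length-2 peak-search window in seconds (within
#'   `ev$test_times`).
#' @param lowpass_hz low-pass cutoff in Hz, or `NULL` for no filtering. The
#'   filter is applied to the full signed trace before the window restriction.
#' @param peak `"signed"` (default: maximum signed correct-class evidence) or
#'   `"abs"` (maximum absolute distance).
#' @return A data.frame of class `"reactivation_table"` with columns
#'   `subject`, `trial`, `train_time`, `peak_time`; the search window, filter
#'   setting and sampling rate are kept as attributes.
#' @export
build_table <- function(ev, window = range(ev$test_times), lowpass_hz = NULL,
                        peak = c("signed", "abs")) {
  stopifnot(inherits(ev, "evidence_tensor"))
  peak <- match.arg(peak)
  d <- dim(ev$values)
  traces <- matrix(ev$values, d[1L] * d[2L], d[3L])
  if (!is.null(lowpass_hz)) traces <- lowpass(traces, lowpass_hz, ev$fs)
  if (peak == "abs") traces <- abs(traces)
  w_idx <- window_indices(ev$test_times, window)
  pk <- max.col(traces[, w_idx, drop = FALSE], ties.method = "first")
  pk_time <- matrix(ev$test_times[w_idx][pk], d[1L], d[2L])
  out <- data.frame(
    subject = rep(ev$subjects, times = d[2L]),
    trial = rep(seq_len(d[1L]), times = d[2L]),
    train_time = rep(ev$train_times, each = d[1L]),
    peak_time = as.vector(pk_time))
  structure(out, window = window, lowpass_hz = lowpass_hz, peak = peak,
            fs = ev$fs, train_times = ev$train_times,
            class = c("reactivation_table", "data.frame"))
}

#' Write / read a reactivation table as TSV
#'
#' Columns: `subject`, `trial`, `train_time_s`, `peak_time_s`.
#'
#' @param table a `"reactivation_table"`.
#' @param path file path.
#' @return `read_reactivation_table` returns a `"reactivation_table"`;
#'   the writer returns `path` invisibly.
#' @export
write_reactivation_table <- function(table, path) {
  df <- data.frame(subject = table$subject, trial = table$trial,
                   train_time_s = table$train_time,
                   peak_time_s = table$peak_time)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reactivation_table
#' @export
read_reactivation_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("subject", "trial", "train_time_s", "peak_time_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reactivation table is missing column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(subject = df$subject, trial = df$trial,
                    train_time = df$train_time_s, peak_time = df$peak_time_s)
  structure(out, train_times = sort(unique(out$train_time)),
            class = c("reactivation_table", "data.frame"))
}

#' Realign epochs on per-trial evidence peaks
#'
#' Builds a realigned dataset by extracting, for every trial and training
#' time, the sensor vector at that trial's reactivation peak. The time axis
#' of the realigned data is inferred from the linear relationship between
#' training time and reactivation time (`inferred_times = beta0 + beta1 *
#' train_times`).
#'
#' @param e the `epochs` object the peaks were measured on.
#' @param table a `"reactivation_table"` whose trials match `e`.
#' @param fit an `"order_fit"` supplying the linear time mapping.
#' @return A list of class `"realigned_epochs"`: `data` (trials x sensors x
#'   training times), `train_times`, `inferred_times`, `labels`, `subjects`.
#' @export
realign <- function(e, table, fit) {
  stopifnot(inherits(e, "epochs"), inherits(table, "reactivation_table"))
  if (is.null(fit$beta0) || is.null(fit$beta1))
    stop("'fit' must carry intercept (beta0) and slope (beta1)")
  tts <- attr(table, "train_times")
  n <- n_trials(e)
  if (!all(sort(unique(table$trial)) == seq_len(n)))
    stop("'table' trials do not match the epochs object")
  out <- array(NA_real_, dim = c(n, n_sensors(e), length(tts)))
  for (j in seq_along(tts)) {
    rows <- table[table$train_time == tts[j], ]
    rows <- rows[order(rows$trial), ]
    s_idx <- vapply(rows$peak_time,
                    function(p) which.min(abs(e$times - p)), integer(1))
    for (i in seq_len(n)) out[i, , j] <- e$data[i, , s_idx[i]]
  }
  structure(list(data = out, train_times = tts,
                 inferred_times = fit$beta0 + fit$beta1 * tts,
                 labels = e$labels, subjects = e$subjects),
            class = "realigned_epochs")
}
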