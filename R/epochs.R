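#' Epoched multichannel recordings
#'
#' The universal exchange object of the package: a trials x sensors x time
#' array of activation values with binary class labels, per-trial subject
#' identifiers, a time axis in seconds, and the sampling rate. All downstream
#' stages (decoding, reactivation timing, order inference, spectral and
#' recurrence analyses) consume and produce this container.
#'
#' @param data numeric array, trials x sensors x time. Non-finite values are
#'   rejected: classifier features must be observed, not imputed.
#' @param labels integer vector of per-trial class labels in `{0, 1}`.
#' @param subjects vector of per-trial subject identifiers.
#' @param times numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced at `1/fs`.
#' @param fs sampling rate in Hz.
#'
#' @return An object of class `"epochs"`: a list with elements `data`,
#'   `labels`, `subjects`, `times`, `fs`.
#' @export
epochs <- function(data, labels, subjects, times, fs) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-d array (trials x sensors x time)")
  if (!all(is.finite(data)))
    stop("'data' contains non-finite values; clean or reject them upstream")
  n_trial <- dim(data)[1L]
  if (length(labels) != n_trial)
    stop("'labels' length (", length(labels), ") does not match trial count (",
         n_trial, ")")
  if (!all(labels %in% c(0L, 1L)))
    stop("'labels' must be binary, coded 0/1")
  if (length(subjects) != n_trial)
    stop("'subjects' length does not match trial count")
  if (length(times) != dim(data)[3L])
    stop("'times' length (", length(times), ") does not match the data time ",
         "dimension (", dim(data)[3L], ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive rate in Hz")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("'times' must be strictly increasing")
    if (max(abs(dt - 1 / fs)) > 1e-9)
      stop("'times' spacing is inconsistent with fs beyond 1e-9")
  }
  structure(
    list(data = data, labels = as.integer(labels), subjects = subjects,
         times = as.numeric(times), fs = fs),
    class = "epochs"
  )
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "epochs: %d trials x %d sensors x %d samples (fs = %g Hz, t = [%.4g, %.4g] s)\n",
    d[1], d[2], d[3], x$fs, x$times[1], x$times[length(x$times)]))
  cat(sprintf("  classes: %d / %d, subjects: %d\n",
              sum(x$labels == 0L), sum(x$labels == 1L),
              length(unique(x$subjects))))
  invisible(x)
}

#' Number of trials / sensors in an epochs object
#' @param x an `epochs` object.
#' @return integer count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' @rdname n_trials
#' @export
n_sensors <- function(x) dim(x$data)[2L]

#' Subset an epochs object by trial
#'
#' @param x an `epochs` object.
#' @param trials integer trial indices to keep.
#' @return an `epochs` object with the selected trials, in the given order.
#' @export
subset_trials <- function(x, trials) {
  epochs(x$data[trials, , , drop = FALSE], x$labels[trials],
         x$subjects[trials], x$times, x$fs)
}

#' Grid indices of a closed time window
#'
#' Windows are closed intervals snapped to the sample grid inclusively at
#' both ends (with a small tolerance for floating-point representation of
#' grid times), so a 70--130 ms window at 300 Hz selects exactly 19 samples.
#'
#' @param times numeric time axis in seconds.
#' @param window length-2 numeric, `c(start, end)` in seconds.
#' @param tol inclusion tolerance in seconds.
#' @return integer vector of indices into `times`.
#' @export
window_indices <- function(times, window, tol = 1e-9) {
  if (length(window) != 2L || window[2] < window[1])
    stop("'window' must be c(start, end) with end >= start")
  idx <- which(times >= window[1] - tol & times <= window[2] + tol)
  if (length(idx) == 0L)
    stop("window [", window[1], ", ", window[2], "] contains no samples")
  idx
}

#' Read and write epochs containers
#'
#' Epochs are serialised as a single R-native file that round-trips all
#' arrays and metadata bit-identically; the event table (trial, class,
#' subject, and onset when recorded) can additionally be exported as TSV for
#' interoperability.
#'
#' @param x an `epochs` object.
#' @param path file path.
#' @return `read_epochs` returns a validated `epochs` object;
#'   `write_epochs` returns `path` invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epochs"))
  saveRDS(unclass(x), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  for (field in c("data", "labels", "subjects", "times", "fs")) {
    if (is.null(obj[[field]]))
      stop("epochs container at '", path, "' is missing field '", field, "'")
  }
  out <- epochs(obj$data, obj$labels, obj$subjects, obj$times, obj$fs)
  extra <- setdiff(names(obj), c("data", "labels", "subjects", "times", "fs"))
  for (field in extra) out[[field]] <- obj[[field]]
  out
}

#' @rdname write_epochs
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "epochs"))
  ev <- data.frame(trial = seq_len(n_trials(x)), class = x$labels,
                   subject = x$subjects)
  if (!is.null(x$onsets)) ev$onset <- x$onsets
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
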