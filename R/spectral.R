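#' Morlet wavelet parameters
#'
#' The complex Morlet wavelet `exp(-t^2 / (2 s^2) + i w t)` with `w = 2 pi
#' f0` and time vector from -0.5 to 0.5 s in steps of `1/fs`, truncated to
#' `support` central samples before convolution. The Gaussian width follows
#' `s = c * 2 pi / w = c / f0` (0.1 s at 10 Hz for one cycle); the
#' alternative convention `s = c / (2 pi f0)` is available via `width_rule`.
#'
#' @param f0 centre frequency in Hz.
#' @param cycles number of cycles `c`.
#' @param fs sampling rate in Hz.
#' @param support number of central wavelet samples retained.
#' @param width_rule `"period"` for `s = c / f0` (default) or `"radian"` for
#'   `s = c / (2 pi f0)`.
#' @return A list of class `"morlet_params"` with the evaluated complex
#'   wavelet in `$wavelet`.
#' @export
morlet_params <- function(f0 = 10, cycles = 1, fs = 300, support = 200L,
                          width_rule = c("period", "radian")) {
  width_rule <- match.arg(width_rule)
  t <- seq(-0.5, 0.5, by = 1 / fs)
  if (support > length(t))
    stop("'support' exceeds the wavelet length (", length(t), " samples)")
  w <- 2 * pi * f0
  s <- if (width_rule == "period") cycles / f0 else cycles / w
  mw <- exp(-t^2 / (2 * s^2) + 1i * w * t)
  centre <- (length(t) + 1L) / 2
  keep <- seq(floor(centre - support / 2 + 1), length.out = support)
  structure(list(f0 = f0, cycles = cycles, fs = fs, support = as.integer(support),
                 t = t[keep], w = w, s = s, wavelet = mw[keep]),
            class = "morlet_params")
}

#' Morlet wavelet power over time
#'
#' Convolves the truncated complex Morlet wavelet with a trace and returns
#' the squared magnitude, aligned to the input samples (zero-phase centre
#' alignment). Samples within half the wavelet support of either edge are
#' contaminated by the boundary and flagged via the `"valid"` attribute.
#'
#' @param trace numeric time series (longer than the wavelet support).
#' @param params a [morlet_params()].
#' @return Numeric power vector, same length as `trace`, with attribute
#'   `"valid"` (logical).
#' @export
morlet_power <- function(trace, params) {
  stopifnot(inherits(params, "morlet_params"))
  n <- length(trace)
  k <- length(params$wavelet)
  if (k > n) stop("wavelet support (", k, ") exceeds trace length (", n, ")")
  full_re <- stats::convolve(trace, rev(Re(params$wavelet)), type = "open")
  full_im <- stats::convolve(trace, rev(Im(params$wavelet)), type = "open")
  offset <- floor((k - 1L) / 2)
  idx <- seq_len(n) + offset
  power <- full_re[idx]^2 + full_im[idx]^2
  half <- ceiling(k / 2)
  valid <- rep(TRUE, n)
  valid[seq_len(min(half, n))] <- FALSE
  valid[seq(max(1L, n - half + 1L), n)] <- FALSE
  attr(power, "valid") <- valid
  power
}

#' Amplitude spectrum with a Hanning taper
#'
#' Multiplies the trace segment inside `taper_window` by a Hanning taper
#' (suppressing edge effects), takes the discrete Fourier transform, and
#' returns the magnitude normalised by the segment length, over the
#' non-negative frequencies.
#'
#' @param trace numeric time series.
#' @param times sample times in seconds.
#' @param taper_window length-2 window in seconds over which the taper is
#'   applied and the spectrum computed.
#' @return A list of class `"spectrum"`: `freqs` (Hz) and `amplitude`.
#' @export
fft_spectrum <- function(trace, times, taper_window = range(times)) {
  idx <- window_indices(times, taper_window)
  n <- length(idx)
  if (n < 2L) stop("taper window must contain at least 2 samples")
  fs <- 1 / mean(diff(times))
  han <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  x <- stats::fft(trace[idx] * han)
  keep <- seq_len(floor(n / 2) + 1L)
  structure(list(freqs = (keep - 1L) * fs / n, amplitude = Mod(x[keep]) / n,
                 n = n, fs = fs, bin_spacing = fs / n),
            class = "spectrum")
}

# complex DFT coefficient of each row of `m` at the bin nearest f0
dft_bin <- function(m, f0, fs) {
  n <- ncol(m)
  k <- round(f0 * n / fs)                       # 0-based bin index
  if (k < 0 || k > n - 1) stop("'f0' outside the resolvable range")
  basis <- exp(-2i * pi * k * (seq_len(n) - 1L) / n)
  as.complex(m %*% basis)
}

#' Magnitude-squared coherence at one frequency
#'
#' Single-window DFT per trial at the bin nearest `f0`; cross- and
#' auto-spectra are averaged over trials before forming the coherence, so the
#' estimate lives in `[0, 1]` and equals 1 only for a trial-wise linear
#' relationship.
#'
#' @param x,y trials x time matrices with matching dimensions (>= 2 trials;
#'   coherence is degenerate at 1 for a single trial).
#' @param f0 target frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return Coherence in `[0, 1]`.
#' @export
coherence_at <- function(x, y, f0, fs) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("'x' and 'y' must have matching dimensions")
  if (nrow(x) < 2L) stop("coherence needs >= 2 trials (degenerate at 1)")
  xs <- dft_bin(x, f0, fs)
  ys <- dft_bin(y, f0, fs)
  sxy <- mean(xs * Conj(ys))
  Mod(sxy)^2 / (mean(Mod(xs)^2) * mean(Mod(ys)^2))
}

#' Permutation test of trace-vs-sensor coherence
#'
#' Compares, per sensor, the coherence between the raw signal and the true
#' reactivation trace with the coherence between the raw signal and the
#' shuffled-classifier trace. The null exchanges the true and shuffled trace
#' within random subsets of trials; two-sided permutation p-values are FDR
#' corrected (Benjamini-Hochberg).
#'
#' @param trace_true,trace_null trials x time matrices of per-trial traces.
#' @param raw an `epochs` object with matching trials.
#' @param f0 frequency of interest in Hz.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param q FDR level.
#' @return A data.frame with one row per sensor: `coh_true`, `coh_null`,
#'   `diff`, `p`, `p_adj`, `significant`.
#' @export
coherence_permutation_test <- function(trace_true, trace_null, raw, f0,
                                       n_perm = 10000L, seed = 1L, q = 0.05) {
  stopifnot(inherits(raw, "epochs"))
  if (n_perm < 100L) stop("'n_perm' must be >= 100")
  trace_true <- as.matrix(trace_true)
  trace_null <- as.matrix(trace_null)
  n <- nrow(trace_true)
  if (n_trials(raw) != n || !all(dim(trace_true) == dim(trace_null)))
    stop("trace and raw trial counts must match")
  fs <- raw$fs
  p_sens <- n_sensors(raw)
  tk <- dft_bin(trace_true, f0, fs)
  nk <- dft_bin(trace_null, f0, fs)
  rk <- matrix(0i, n, p_sens)
  for (s in seq_len(p_sens))
    rk[, s] <- dft_bin(matrix(raw$data[, s, ], n), f0, fs)
  syy <- colMeans(Mod(rk)^2)

  coh_of <- function(a) {
    sxy <- colMeans(Conj(rk) * a)
    Mod(sxy)^2 / (mean(Mod(a)^2) * syy)
  }
  coh_true <- coh_of(tk)
  coh_null <- coh_of(nk)
  obs <- coh_true - coh_null

  set.seed(seed)
  exceed <- integer(p_sens)
  for (b in seq_len(n_perm)) {
    swap <- stats::runif(n) < 0.5
    a <- tk; a[swap] <- nk[swap]
    bb <- nk; bb[swap] <- tk[swap]
    d <- coh_of(a) - coh_of(bb)
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p <- (exceed + 1) / (n_perm + 1)
  fdr <- fdr_correct(p, q)
  data.frame(sensor = seq_len(p_sens), coh_true = coh_true,
             coh_null = coh_null, diff = obs, p = p,
             p_adj = fdr$adjusted, significant = fdr$reject)
}

#' Cross-correlation lag between two signals
#'
#' The lag maximising the Pearson-normalised cross-correlation within
#' `max_lag`. A positive lag means `x` leads `y` (the content of `y` appears
#' later). When trial-resolved matrices are supplied, the lag is estimated on
#' the trial means and a percentile bootstrap CI over trials is attached.
#'
#' @param x,y numeric vectors of equal length, or trials x time matrices.
#' @param max_lag maximum absolute lag in seconds.
#' @param fs sampling rate in Hz.
#' @param n_boot bootstrap samples for the CI (matrices only; 0 disables).
#' @param seed integer seed for the bootstrap.
#' @return Lag in seconds; for trial-resolved input, attributes `"ci"` and
#'   `"n_boot"` are attached.
#' @export
xcorr_lag <- function(x, y, max_lag, fs, n_boot = 0L, seed = 1L) {
  trialwise <- !is.null(dim(x))
  xm <- if (trialwise) colMeans(x) else x
  ym <- if (trialwise) colMeans(y) else y
  if (length(xm) != length(ym)) stop("'x' and 'y' must have equal lengths")
  lag_of <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("flat signal: cross-correlation undefined")
    n <- length(a)
    lags <- seq(-floor(max_lag * fs), floor(max_lag * fs))
    r <- vapply(lags, function(l) {
      if (l >= 0) stats::cor(a[seq_len(n - l)], b[seq_len(n - l) + l])
      else stats::cor(a[seq_len(n + l) - l], b[seq_len(n + l)])
    }, numeric(1))
    lags[which.max(r)] / fs
  }
  est <- lag_of(xm, ym)
  if (trialwise && n_boot > 0L) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(x), replace = TRUE)
      tryCatch(lag_of(colMeans(x[idx, , drop = FALSE]),
                      colMeans(y[idx, , drop = FALSE])),
               error = function(e) NA_real_)
    }, numeric(1))
    attr(est, "ci") <- unname(stats::quantile(boots, c(0.025, 0.975),
                                              na.rm = TRUE))
    attr(est, "n_boot") <- n_boot
  }
  est
}
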