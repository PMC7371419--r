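# interior local extrema of a series; plateaus count once, at their first
# sample, and endpoints are never extrema
local_extrema <- function(x) {
  s <- sign(diff(x))
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- last else last <- s[i]
  }
  if (length(s) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  a <- s[-length(s)]
  b <- s[-1L]
  list(maxima = which(a > 0 & b < 0) + 1L,
       minima = which(a < 0 & b > 0) + 1L)
}

n_extrema <- function(x) {
  e <- local_extrema(x)
  length(e$maxima) + length(e$minima)
}

# cubic-spline envelope through extrema, with mirror extension of up to two
# extrema beyond each boundary to tame edge divergence
spline_envelope <- function(idx, val, n) {
  if (length(idx) == 0L) return(rep(0, n))
  if (length(idx) == 1L) return(rep(val, n))
  k <- min(2L, length(idx))
  lp <- 2 - rev(idx[seq_len(k)]); lv <- rev(val[seq_len(k)])
  rp <- 2 * n - rev(rev(idx)[seq_len(k)]); rv <- rev(rev(val)[seq_len(k)])
  stats::spline(c(lp, idx, rp), c(lv, val, rv), xout = seq_len(n))$y
}

#' Empirical mode decomposition
#'
#' Standard sifting: cubic-spline envelopes through local maxima and minima,
#' mean-envelope subtraction iterated until the normalised squared change
#' between successive sifts falls below `sd_stop` (or `max_sifts` is
#' reached); intrinsic mode functions (IMFs) are extracted until the residual
#' has fewer than two interior extrema. EMD identifies oscillations without
#' assuming they are sinusoidal, which suits reactivation traces whose
#' increasing and decreasing phases need not be symmetric.
#'
#' @param trace numeric time series.
#' @param times optional sample times (recorded for downstream phase
#'   segmentation).
#' @param max_imfs maximum number of IMFs extracted.
#' @param sd_stop sifting stop criterion.
#' @param max_sifts maximum sift iterations per IMF.
#' @return A list of class `"imf_set"`: `imfs` (list of series), `residual`,
#'   `times`. The IMFs plus residual reconstruct the input exactly.
#' @export
emd <- function(trace, times = NULL, max_imfs = 10L, sd_stop = 0.2,
                max_sifts = 50L) {
  if (length(trace) < 8L) stop("trace too short for EMD (need >= 8 samples)")
  r <- as.numeric(trace)
  imfs <- list()
  while (length(imfs) < max_imfs && n_extrema(r) >= 2L) {
    h <- r
    for (it in seq_len(max_sifts)) {
      e <- local_extrema(h)
      if (length(e$maxima) < 1L || length(e$minima) < 1L) break
      upper <- spline_envelope(e$maxima, h[e$maxima], length(h))
      lower <- spline_envelope(e$minima, h[e$minima], length(h))
      m <- (upper + lower) / 2
      sdv <- sum(m^2) / (sum(h^2) + .Machine$double.eps)
      h <- h - m
      if (sdv < sd_stop) break
    }
    imfs <- c(imfs, list(h))
    r <- r - h
  }
  structure(list(imfs = imfs, residual = r, times = times),
            class = "imf_set")
}

#' Select the IMF matching an expected extrema count
#'
#' For a target oscillation of frequency f over a window of length T, one
#' expects `2 f T` interior extrema (eight for 10 Hz over 400 ms). The IMF
#' whose interior extrema count is closest to `expected_extrema` is selected;
#' ties go to the lower-index (faster) IMF.
#'
#' @param imf_set an `"imf_set"`.
#' @param expected_extrema target count (default 8).
#' @return A list: `imf`, `extrema_idx` (sorted interior extrema indices),
#'   `extrema_times` (when the set carries times), `count`, `index`.
#' @export
select_imf <- function(imf_set, expected_extrema = 8L) {
  stopifnot(inherits(imf_set, "imf_set"))
  if (length(imf_set$imfs) == 0L) stop("IMF set is empty")
  counts <- vapply(imf_set$imfs, n_extrema, integer(1))
  index <- which.min(abs(counts - expected_extrema))
  imf <- imf_set$imfs[[index]]
  e <- local_extrema(imf)
  idx <- sort(c(e$maxima, e$minima))
  list(imf = imf, extrema_idx = idx,
       extrema_times = if (!is.null(imf_set$times)) imf_set$times[idx],
       count = counts[index], index = index)
}

phase_set <- function(t_start, t_end, direction) {
  df <- data.frame(t_start = t_start, t_end = t_end, direction = direction)
  if (nrow(df) > 1L) {
    if (any(df$t_start[-1L] < df$t_end[-nrow(df)] - 1e-9))
      stop("phases must be non-overlapping and in time order")
    if (any(df$direction[-1L] == df$direction[-nrow(df)]))
      stop("phase directions must alternate")
  }
  structure(df, class = c("phase_set", "data.frame"))
}

#' Segment an IMF into increasing and decreasing phases
#'
#' Phases are the periods between subsequent interior extrema of the selected
#' IMF; the direction of each phase is the sign of the IMF change across it
#' (increasing = feedback, decreasing = feed-forward, in the reactivation
#' trace reading).
#'
#' @param imf numeric IMF series.
#' @param extrema_idx sorted interior extrema indices (>= 2).
#' @param times sample times in seconds.
#' @return A data.frame of class `"phase_set"` with columns `t_start`,
#'   `t_end`, `direction`.
#' @export
segment_phases <- function(imf, extrema_idx, times) {
  if (length(extrema_idx) < 2L) stop("need >= 2 extrema to segment phases")
  a <- extrema_idx[-length(extrema_idx)]
  b <- extrema_idx[-1L]
  phase_set(times[a], times[b],
            ifelse(imf[b] > imf[a], "increasing", "decreasing"))
}

#' Fixed-frequency phase segmentation
#'
#' Tiles a window with contiguous alternating phases of half a period each:
#' 10 Hz over 400 ms gives four feed-forward and four feedback phases of
#' 50 ms.
#'
#' @param f oscillation frequency in Hz.
#' @param window length-2 window in seconds (at least half a period long).
#' @param phase0 direction of the first phase.
#' @return A `"phase_set"`.
#' @export
fixed_freq_phases <- function(f, window,
                              phase0 = c("decreasing", "increasing")) {
  phase0 <- match.arg(phase0)
  half <- 1 / (2 * f)
  n <- floor(diff(window) / half + 1e-9)
  if (n < 1L) stop("window is shorter than half a period of ", f, " Hz")
  starts <- window[1] + (seq_len(n) - 1L) * half
  dirs <- rep(c(phase0, setdiff(c("increasing", "decreasing"), phase0)),
              length.out = n)
  phase_set(starts, starts + half, dirs)
}

#' Phase-pair slope matrix
#'
#' Cell (i, j) is the pooled OLS slope of reactivation time (peak evidence
#' searched within test phase i) on training time (restricted to train phase
#' j), over all trials (and, when a list of per-subject evidence tensors is
#' given, all subjects). Per-trial slope contributions are retained so the
#' Recurrence Index can be bootstrapped over trials cheaply.
#'
#' @param ev an `"evidence_tensor"`, or a list of them sharing time grids
#'   (e.g. one per subject).
#' @param train_phases,test_phases `"phase_set"` objects.
#' @param lowpass_hz optional low-pass cutoff applied to the evidence traces
#'   before the peak search (within-perception analyses typically use none).
#' @param pooling `"trials"` (pool all points; default) or `"subjects"`
#'   (average per-subject slopes).
#' @return A list of class `"slope_matrix"`: `slopes` (test x train phases),
#'   `n_points`, `trial_contrib` (trials x test x train per-trial slope
#'   contributions, cell mean = slope), `subjects`, `labels`, `train_phases`,
#'   `test_phases`.
#' @export
phase_slopes <- function(ev, train_phases, test_phases, lowpass_hz = NULL,
                         pooling = c("trials", "subjects")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(train_phases, "phase_set"),
            inherits(test_phases, "phase_set"))
  tensors <- if (inherits(ev, "evidence_tensor")) list(ev) else ev
  stopifnot(all(vapply(tensors, inherits, logical(1), "evidence_tensor")))
  tt <- tensors[[1L]]$train_times
  te <- tensors[[1L]]$test_times
  for (x in tensors[-1L]) {
    if (max(abs(x$train_times - tt)) > 1e-9 || max(abs(x$test_times - te)) > 1e-9)
      stop("all evidence tensors must share the same time grids")
  }
  traces <- lapply(tensors, function(x) {
    d <- dim(x$values)
    m <- matrix(x$values, d[1L] * d[2L], d[3L])
    if (!is.null(lowpass_hz)) m <- lowpass(m, lowpass_hz, x$fs)
    m
  })
  n_per <- vapply(tensors, function(x) dim(x$values)[1L], integer(1))
  n_tot <- sum(n_per)
  subjects <- unlist(lapply(tensors, `[[`, "subjects"))
  labels <- unlist(lapply(tensors, `[[`, "labels"))
  ni <- nrow(test_phases)
  nj <- nrow(train_phases)
  tol <- 1e-9

  slopes <- matrix(NA_real_, ni, nj)
  n_points <- matrix(0L, ni, nj)
  contrib <- array(NA_real_, dim = c(n_tot, ni, nj))

  for (i in seq_len(ni)) {
    w_idx <- which(te >= test_phases$t_start[i] - tol &
                     te <= test_phases$t_end[i] + tol)
    if (length(w_idx) == 0L) next
    # peak time per (trial, train time), searched inside test phase i
    pk <- lapply(seq_along(tensors), function(s) {
      d <- dim(tensors[[s]]$values)
      p <- max.col(traces[[s]][, w_idx, drop = FALSE], ties.method = "first")
      matrix(te[w_idx][p], d[1L], d[2L])
    })
    pk <- do.call(rbind, pk)                     # n_tot x n_train_times
    for (j in seq_len(nj)) {
      end_tol <- if (j == nj) tol else -tol      # shared boundaries go left
      cols <- which(tt >= train_phases$t_start[j] - tol &
                      tt < train_phases$t_end[j] + end_tol)
      if (length(unique(tt[cols])) < 2L) next
      x <- tt[cols]
      xc <- x - mean(x)
      sxx <- sum(xc^2)
      ct <- as.numeric(pk[, cols, drop = FALSE] %*% xc) / sxx
      contrib[, i, j] <- ct
      n_points[i, j] <- n_tot * length(cols)
      slopes[i, j] <- if (pooling == "trials") mean(ct) else
        mean(tapply(ct, subjects, mean))
    }
  }
  structure(list(slopes = slopes, n_points = n_points,
                 trial_contrib = contrib, subjects = subjects,
                 labels = labels, train_phases = train_phases,
                 test_phases = test_phases, pooling = pooling),
            class = "slope_matrix")
}

#' Hypothesis matrix for recurrent processing
#'
#' Under recurrent processing, classifiers trained in a phase of one
#' direction reactivate in the same order (+1) within test phases of the same
#' direction and in reversed order (-1) within phases of the opposite
#' direction. With the same alternating phase set on both axes this is a
#' checkerboard with a +1 diagonal.
#'
#' @param train_phases,test_phases `"phase_set"` objects.
#' @return test x train matrix of +1/-1.
#' @export
hypothesis_matrix <- function(train_phases, test_phases) {
  stopifnot(inherits(train_phases, "phase_set"),
            inherits(test_phases, "phase_set"))
  outer(test_phases$direction, train_phases$direction,
        function(a, b) ifelse(a == b, 1, -1))
}

#' Recurrence Index
#'
#' The dot product between the vectorised hypothesis matrix and the empirical
#' phase-pair slope matrix: positive when the data show the hypothesised
#' alternation of information-flow direction, zero when there is none,
#' negative for the opposite pattern. Uncertainty comes from a percentile
#' bootstrap over trials (using the per-trial slope contributions retained by
#' [phase_slopes()]); a permutation p-value is computed when slope matrices
#' from shuffled-label pipeline runs are supplied.
#'
#' @param slopes a `"slope_matrix"`, or a plain numeric matrix (no bootstrap).
#' @param hypothesis +1/-1 matrix of matching shape.
#' @param n_boot bootstrap samples (0 disables).
#' @param level CI level.
#' @param seed integer seed.
#' @param null_slopes optional list of slope matrices from shuffled-label
#'   runs; the permutation p is the upper tail probability of the observed RI
#'   under those nulls.
#' @return A list of class `"recurrence_result"`: `ri`, `bootstrap_ci`,
#'   `permutation_p`, `hypothesis`, `n_boot`, `seed`, `null_ri`.
#' @export
recurrence_index <- function(slopes, hypothesis, n_boot = 10000L,
                             level = 0.95, seed = 1L, null_slopes = NULL) {
  sm <- if (inherits(slopes, "slope_matrix")) slopes$slopes else as.matrix(slopes)
  if (!all(dim(sm) == dim(hypothesis)))
    stop("slope and hypothesis matrices must have the same shape")
  mask <- !is.na(sm)
  ri <- sum(hypothesis[mask] * sm[mask])

  ci <- c(NA_real_, NA_real_)
  if (inherits(slopes, "slope_matrix") && n_boot > 0L) {
    cmat <- matrix(slopes$trial_contrib, dim(slopes$trial_contrib)[1L])
    hv <- as.vector(hypothesis)
    keep <- !is.na(cmat[1L, ]) & as.vector(mask)
    g <- as.numeric(cmat[, keep, drop = FALSE] %*% hv[keep])
    set.seed(seed)
    n <- length(g)
    boots <- vapply(seq_len(n_boot), function(b)
      mean(g[sample.int(n, replace = TRUE)]), numeric(1))
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  }

  null_ri <- NULL
  perm_p <- NA_real_
  if (!is.null(null_slopes)) {
    null_ri <- vapply(null_slopes, function(s) {
      m <- if (inherits(s, "slope_matrix")) s$slopes else as.matrix(s)
      msk <- !is.na(m)
      sum(hypothesis[msk] * m[msk])
    }, numeric(1))
    perm_p <- (1 + sum(null_ri >= ri)) / (length(null_ri) + 1)
  }
  structure(list(ri = ri, bootstrap_ci = ci, permutation_p = perm_p,
                 hypothesis = hypothesis, n_boot = n_boot, seed = seed,
                 null_ri = null_ri),
            class = "recurrence_result")
}

#' @export
print.recurrence_result <- function(x, ...) {
  cat(sprintf("Recurrence Index = %.4g", x$ri))
  if (!any(is.na(x$bootstrap_ci)))
    cat(sprintf(" (95%% bootstrap CI %.4g to %.4g)", x$bootstrap_ci[1],
                x$bootstrap_ci[2]))
  if (!is.na(x$permutation_p))
    cat(sprintf(", permutation p = %.3g", x$permutation_p))
  cat("\n")
  invisible(x)
}

#' Near- versus far-phase Recurrence Index
#'
#' Compares the normalised per-cell RI contribution (hypothesis x slope,
#' divided by the number of cells in the group) of cells on or next to the
#' diagonal of the slope matrix with all remaining cells. A higher near-phase
#' value means recurrence is restricted to neighbouring cycles, as expected
#' when representations drift across successive recurrent updates.
#'
#' @param slopes a `"slope_matrix"` (at least 3 x 3).
#' @param hypothesis matching +1/-1 matrix.
#' @param n_boot bootstrap samples for the difference p-value.
#' @param seed integer seed.
#' @return A list: `near`, `far`, `p` (two-sided bootstrap p for the
#'   difference; `NA` without trial contributions).
#' @export
neighbor_ri <- function(slopes, hypothesis, n_boot = 2000L, seed = 1L) {
  sm <- if (inherits(slopes, "slope_matrix")) slopes$slopes else as.matrix(slopes)
  if (nrow(sm) < 3L || ncol(sm) < 3L)
    stop("neighbour analysis needs at least a 3 x 3 slope matrix")
  if (!all(dim(sm) == dim(hypothesis)))
    stop("slope and hypothesis matrices must have the same shape")
  idx <- abs(row(sm) - col(sm)) <= 1L
  g <- hypothesis * sm
  near_cells <- which(idx & !is.na(sm))
  far_cells <- which(!idx & !is.na(sm))
  near <- sum(g[near_cells]) / length(near_cells)
  far <- sum(g[far_cells]) / length(far_cells)

  p <- NA_real_
  if (inherits(slopes, "slope_matrix") && n_boot > 0L) {
    cmat <- matrix(slopes$trial_contrib, dim(slopes$trial_contrib)[1L])
    hv <- as.vector(hypothesis)
    gn <- as.numeric(cmat[, near_cells, drop = FALSE] %*% hv[near_cells]) /
      length(near_cells)
    gf <- as.numeric(cmat[, far_cells, drop = FALSE] %*% hv[far_cells]) /
      length(far_cells)
    set.seed(seed)
    n <- length(gn)
    d <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      mean(gn[i]) - mean(gf[i])
    }, numeric(1))
    p <- min(1, max(1 / n_boot, 2 * min(mean(d <= 0), mean(d >= 0))))
  }
  list(near = near, far = far, p = p)
}
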