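#' Percentile bootstrap confidence interval
#'
#' Resamples the supplied units (vector elements, or rows of a matrix /
#' data.frame — trials, by default, in pipeline use) with replacement and
#' returns the percentile interval of the statistic.
#'
#' @param data numeric vector, matrix or data.frame of resampling units.
#' @param statistic function mapping a resampled `data` to a scalar.
#' @param n_boot number of bootstrap samples.
#' @param level CI level.
#' @param seed integer seed.
#' @return A list of class `"bootstrap_result"`: `estimate`, `ci`, `level`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 10000L, level = 0.95,
                         seed = 1L) {
  take <- function(d, idx) {
    if (is.null(dim(d))) d[idx] else d[idx, , drop = FALSE]
  }
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 2L) stop("need >= 2 resampling units")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    statistic(take(data, sample.int(n, replace = TRUE))), numeric(1))
  alpha <- (1 - level) / 2
  structure(list(estimate = statistic(data),
                 ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
                 level = level, n_boot = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("estimate %.4g, %g%% bootstrap CI [%.4g, %.4g] (n_boot = %d)\n",
              x$estimate, 100 * x$level, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Paired bootstrap p-value
#'
#' Two-sided p-value for a pairwise comparison, obtained by bootstrapping the
#' difference of the statistic between two matched conditions: the fraction
#' of bootstrap differences crossing zero, doubled and clipped to
#' `[1/n_boot, 1]`.
#'
#' @param a,b matched numeric vectors.
#' @param statistic scalar statistic applied to each condition.
#' @param n_boot number of bootstrap samples.
#' @param seed integer seed.
#' @return p-value in `[1/n_boot, 1]`.
#' @export
paired_bootstrap_p <- function(a, b, statistic = mean, n_boot = 10000L,
                               seed = 1L) {
  if (length(a) != length(b)) stop("'a' and 'b' must have matched lengths")
  set.seed(seed)
  n <- length(a)
  d <- vapply(seq_len(n_boot), function(k) {
    idx <- sample.int(n, replace = TRUE)
    statistic(a[idx]) - statistic(b[idx])
  }, numeric(1))
  min(1, max(1 / n_boot, 2 * min(mean(d <= 0), mean(d >= 0))))
}

#' Permute class labels
#'
#' A uniform random permutation: erases the label-data association (and with
#' it stimulus information) while preserving the label multiset and the
#' temporal structure of the data.
#'
#' @param labels vector of labels.
#' @param seed integer seed.
#' @return Permuted labels.
#' @export
permute_labels <- function(labels, seed) {
  set.seed(seed)
  labels[sample.int(length(labels))]
}

#' Benjamini-Hochberg FDR correction
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param q FDR level for the rejection flags.
#' @return A list: `adjusted` (BH-adjusted p-values) and `reject` (logical,
#'   `adjusted <= q`).
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}
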