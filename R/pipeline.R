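#' Pipeline configuration
#'
#' Defaults follow the analysis the package implements: perception models
#' trained on the 70--130 ms feed-forward window (19 grid points at 300 Hz),
#' 5-fold cross-validation, LDA shrinkage 0.05, a 30 Hz low-pass on the
#' evidence traces for across-epoch (imagery-style) reactivation timing and
#' no filter for within-epoch (perception-phase) analyses, 10 Hz phase
#' segmentation over the first 400 ms, and 10000 bootstrap samples.
#'
#' @param train_window training window in seconds.
#' @param test_window evidence window in seconds (`NULL` = full test epoch).
#' @param folds number of cross-validation folds.
#' @param gamma LDA shrinkage weight.
#' @param lowpass low-pass cutoff in Hz for reactivation traces (`NULL` for
#'   none).
#' @param phases phase segmentation spec: `"emd"` or `"freq:<Hz>"`.
#' @param phase_window window for phase segmentation, seconds.
#' @param boot bootstrap samples.
#' @param n_null shuffled-label pipeline runs for the recurrence null.
#' @param seed integer master seed; every stochastic step derives its own
#'   sub-seed from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(train_window = c(0.070, 0.130),
                            test_window = NULL, folds = 5L, gamma = 0.05,
                            lowpass = 30, phases = "freq:10",
                            phase_window = c(0, 0.4), boot = 10000L,
                            n_null = 1L, seed = 1L) {
  structure(list(train_window = train_window, test_window = test_window,
                 folds = as.integer(folds), gamma = gamma, lowpass = lowpass,
                 phases = phases, phase_window = phase_window,
                 boot = as.integer(boot), n_null = as.integer(n_null),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

manifest <- function(config, seed) {
  list(config = unclass(config), seed = seed,
       package_version = as.character(utils::packageVersion("reactime")))
}

# rank correlation between training time and the test time of maximum
# accuracy per training time: a monotone ridge in a trial-averaged matrix
# gives |rho| near 1, jitter-smeared matrices give values near 0. The
# reversal report applies this per subject (accuracy is a within-subject
# quantity) and summarises with the subject mean.
accuracy_ridge_stat <- function(acc) {
  stopifnot(inherits(acc, "accuracy_matrix"))
  arg <- acc$test_times[max.col(acc$values, ties.method = "first")]
  suppressWarnings(stats::cor(acc$train_times, arg, method = "spearman"))
}

#' Reversal (order-of-reactivation) analysis
#'
#' The package's first headline analysis: decode each subject with
#' time-point-specific shrinkage-LDA models, convert the cross-validated
#' evidence to per-trial reactivation times, and infer the order of
#' reactivation by fixed- and mixed-effects regression, with a shuffled-label
#' control. A negative slope means the training sequence replays in reversed
#' order; the trial-averaged accuracy matrix and its ridge statistic are
#' included to show what averaging obscures under onset jitter.
#'
#' @param train,test paired `epochs` objects (training and generalisation
#'   epochs).
#' @param config a [pipeline_config()].
#' @param lmm fit the mixed-model candidate set as well.
#' @param shuffle run the shuffled-label control.
#' @param subject_level add the subject-averaged fit (needs >= 3 subjects).
#' @return A list of class `"reversal_report"`: `table`, `fit_lm`,
#'   `selection` (mixed models), `subject_fit`, `null_fit`, `accuracy`
#'   (subject-mean matrix), `ridge_rho`, `manifest`.
#' @export
run_reversal_analysis <- function(train, test, config = pipeline_config(),
                                  lmm = TRUE, shuffle = TRUE,
                                  subject_level = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  test_window <- config$test_window %||% range(test$times)
  subj <- unique(train$subjects)
  tabs <- vector("list", length(subj))
  acc_sum <- NULL
  ridge <- numeric(length(subj))
  for (k in seq_along(subj)) {
    idx <- which(train$subjects == subj[k])
    ev <- crossval_evidence(subset_trials(train, idx),
                            subset_trials(test, idx),
                            train_times = train$times[
                              window_indices(train$times, config$train_window)],
                            test_window = test_window,
                            k_folds = config$folds, gamma = config$gamma,
                            seed = sub_seed(config$seed, k))
    acc <- accuracy_matrix(ev)
    ridge[k] <- accuracy_ridge_stat(acc)
    acc_sum <- if (is.null(acc_sum)) acc$values else acc_sum + acc$values
    tab <- build_table(ev, window = test_window, lowpass_hz = config$lowpass)
    tab$trial <- idx[tab$trial]
    tabs[[k]] <- tab
  }
  table <- do.call(rbind, tabs)
  table <- structure(table, train_times = sort(unique(table$train_time)),
                     window = test_window, lowpass_hz = config$lowpass,
                     class = c("reactivation_table", "data.frame"))
  acc_mean <- structure(
    list(values = acc_sum / length(subj),
         train_times = sort(unique(table$train_time)),
         test_times = test$times[window_indices(test$times, test_window)],
         n_trials = n_trials(test)),
    class = "accuracy_matrix")

  fit_lm <- fit_order_lm(table)
  selection <- if (lmm) fit_order_lmm(table) else NULL
  subject_fit <- if (subject_level) subject_level_fit(table) else NULL
  null_fit <- NULL
  if (shuffle) {
    settings <- list(train_window = config$train_window,
                     test_window = test_window, k_folds = config$folds,
                     gamma = config$gamma, lowpass_hz = config$lowpass)
    null_fit <- shuffled_control(train, test, settings,
                                 seed = sub_seed(config$seed, 9001L))
  }
  structure(list(table = table, fit_lm = fit_lm, selection = selection,
                 subject_fit = subject_fit, null_fit = null_fit,
                 accuracy = acc_mean, ridge_by_subject = ridge,
                 ridge_rho = mean(ridge),
                 manifest = manifest(config, config$seed)),
            class = "reversal_report")
}

#' @export
print.reversal_report <- function(x, ...) {
  cat("Reversal analysis\n-----------------\n")
  print(x$fit_lm)
  if (!is.null(x$selection)) {
    w <- x$selection$candidates[[x$selection$winner]]
    cat(sprintf("mixed model winner [%s]: beta1 = %.4g, t(%s) = %.3f, p = %.3g\n",
                w$random_structure, w$beta1, format(w$dof), w$t_stat,
                w$p_value))
  }
  if (!is.null(x$null_fit))
    cat(sprintf("shuffled-label control: beta1 = %.4g, p = %.3g\n",
                x$null_fit$beta1, x$null_fit$p_value))
  cat(sprintf("accuracy-ridge rank correlation: %.3f\n", x$ridge_rho))
  invisible(x)
}

parse_phases <- function(spec, window, trace = NULL, trace_times = NULL,
                         expected_extrema = 8L) {
  if (identical(spec, "emd")) {
    if (is.null(trace))
      stop("EMD phase segmentation needs a reactivation trace")
    dec <- emd(trace, times = trace_times)
    sel <- select_imf(dec, expected_extrema)
    if (length(sel$extrema_idx) < 2L)
      stop("selected IMF has fewer than 2 extrema; cannot segment phases")
    return(segment_phases(sel$imf, sel$extrema_idx, trace_times))
  }
  if (grepl("^freq:", spec)) {
    f <- as.numeric(sub("^freq:", "", spec))
    return(fixed_freq_phases(f, window))
  }
  stop("unknown phase spec '", spec, "' (use \"emd\" or \"freq:<Hz>\")")
}

# per-subject cross-validated evidence tensors for a within-epoch analysis
subject_tensors <- function(e, train_times, test_window, config, seed) {
  subj <- unique(e$subjects)
  lapply(seq_along(subj), function(k) {
    idx <- which(e$subjects == subj[k])
    crossval_evidence(subset_trials(e, idx), train_times = train_times,
                      test_window = test_window, k_folds = config$folds,
                      gamma = config$gamma, seed = sub_seed(seed, k))
  })
}

#' Recurrence (within-epoch phase) analysis
#'
#' The package's second headline analysis: train classifiers on every time
#' point of the phase window, compute per-trial reactivation times within
#' each phase, regress them on training time per phase pair, and quantify the
#' hypothesised alternation of information-flow direction with the Recurrence
#' Index, bootstrapped over trials and compared against shuffled-label runs.
#'
#' @param e an `epochs` object (a within-epoch analysis: the same epochs are
#'   decoded and tested).
#' @param config a [pipeline_config()]; `config$phases` selects EMD or
#'   fixed-frequency segmentation over `config$phase_window`, and
#'   `config$lowpass` is deliberately ignored here (within-epoch analyses use
#'   no filter unless `config$phases_lowpass` is set).
#' @return A list of class `"recurrence_report"`: `phases`, `slopes`,
#'   `hypothesis`, `ri` (with bootstrap CI and permutation p when
#'   `config$n_null > 0`), `null_ri` (list of shuffled-run results),
#'   `neighbor`, `manifest`.
#' @export
run_recurrence_analysis <- function(e, config = pipeline_config()) {
  stopifnot(inherits(e, "epochs"), inherits(config, "pipeline_config"))
  window <- config$phase_window
  train_times <- e$times[window_indices(e$times, window)]
  tensors <- subject_tensors(e, train_times, window, config, config$seed)

  trace <- NULL
  if (identical(config$phases, "emd")) {
    # mean reactivation trace over trials and subjects, per training time
    tab <- do.call(rbind, lapply(tensors, build_table, window = window))
    trace <- stats::aggregate(peak_time ~ train_time, tab, mean)$peak_time
  }
  phases <- parse_phases(config$phases, window, trace, train_times)
  hyp <- hypothesis_matrix(phases, phases)
  slopes <- phase_slopes(tensors, phases, phases)

  null_slopes <- list()
  if (config$n_null > 0L) {
    for (b in seq_len(config$n_null)) {
      en <- e
      set.seed(sub_seed(config$seed, 5000L + b))
      for (s in unique(en$subjects)) {
        idx <- which(en$subjects == s)
        en$labels[idx] <- en$labels[idx][sample.int(length(idx))]
      }
      tn <- subject_tensors(en, train_times, window, config,
                            sub_seed(config$seed, 6000L + b))
      null_slopes[[b]] <- phase_slopes(tn, phases, phases)
    }
  }
  ri <- recurrence_index(slopes, hyp, n_boot = config$boot,
                         seed = sub_seed(config$seed, 7000L),
                         null_slopes = if (length(null_slopes)) null_slopes)
  null_ri <- lapply(seq_along(null_slopes), function(b)
    recurrence_index(null_slopes[[b]], hyp, n_boot = config$boot,
                     seed = sub_seed(config$seed, 7100L + b)))
  neighbor <- if (nrow(slopes$slopes) >= 3L)
    neighbor_ri(slopes, hyp, seed = sub_seed(config$seed, 7200L)) else NULL
  structure(list(phases = phases, slopes = slopes, hypothesis = hyp, ri = ri,
                 null_ri = null_ri, neighbor = neighbor,
                 manifest = manifest(config, config$seed)),
            class = "recurrence_report")
}

#' @export
print.recurrence_report <- function(x, ...) {
  cat("Recurrence analysis\n-------------------\n")
  cat(sprintf("%d phases (%s)\n", nrow(x$phases),
              paste(x$phases$direction[1:min(4, nrow(x$phases))],
                    collapse = "/")))
  print(x$ri)
  if (length(x$null_ri))
    cat(sprintf("shuffled-label RI: %s\n",
                paste(sprintf("%.3g [%.3g, %.3g]",
                              vapply(x$null_ri, `[[`, numeric(1), "ri"),
                              vapply(x$null_ri, function(r) r$bootstrap_ci[1],
                                     numeric(1)),
                              vapply(x$null_ri, function(r) r$bootstrap_ci[2],
                                     numeric(1))),
                      collapse = "; ")))
  if (!is.null(x$neighbor))
    cat(sprintf("near-diagonal RI %.4g vs distant %.4g (p = %.3g)\n",
                x$neighbor$near, x$neighbor$far, x$neighbor$p))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serialises the numeric content of a reversal or recurrence report (fits,
#' BIC table, RI, CIs, manifest) to JSON; large per-trial tables are written
#' separately with [write_reactivation_table()].
#'
#' @param report a `"reversal_report"` or `"recurrence_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip_fit <- function(f) if (is.null(f)) NULL else
    f[c("beta0", "beta1", "se0", "se1", "t_stat", "dof", "p_value",
        "random_structure", "bic", "n")]
  out <- if (inherits(report, "reversal_report")) {
    list(analysis = "reversal",
         fit_lm = strip_fit(report$fit_lm),
         mixed_winner = if (!is.null(report$selection))
           strip_fit(report$selection$candidates[[report$selection$winner]]),
         bic_table = report$selection$bic_table,
         null_fit = strip_fit(report$null_fit),
         ridge_rho = report$ridge_rho,
         manifest = report$manifest)
  } else if (inherits(report, "recurrence_report")) {
    list(analysis = "recurrence",
         phases = as.data.frame(report$phases),
         slopes = report$slopes$slopes,
         hypothesis = report$hypothesis,
         ri = report$ri$ri, bootstrap_ci = report$ri$bootstrap_ci,
         permutation_p = report$ri$permutation_p,
         null_ri = vapply(report$null_ri, `[[`, numeric(1), "ri"),
         neighbor = report$neighbor,
         manifest = report$manifest)
  } else stop("unsupported report class")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
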