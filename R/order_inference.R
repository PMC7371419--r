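#' Order inference by ordinary least squares
#'
#' Regresses per-trial reactivation times on training time over all (trial,
#' training time) points. The slope sign is the direction verdict: positive
#' means the test sequence replays in the same order as training, negative
#' means the order is reversed. A slope magnitude near the generating
#' time-compression factor indicates replay at the corresponding speed.
#'
#' @param table a `"reactivation_table"`.
#' @return A list of class `"order_fit"`: `beta0`, `beta1`, `se0`, `se1`,
#'   `t_stat`, `dof`, `p_value` (two-sided, from the t distribution with
#'   residual degrees of freedom), `random_structure`, `bic`, `n`,
#'   `converged`.
#' @export
fit_order_lm <- function(table) {
  stopifnot(inherits(table, "reactivation_table"))
  if (length(unique(table$train_time)) < 2L)
    stop("need >= 2 distinct training times (constant predictor)")
  fit <- stats::lm(peak_time ~ train_time, data = table)
  co <- summary(fit)$coefficients
  dof <- fit$df.residual
  structure(list(beta0 = unname(co[1, 1]), beta1 = unname(co[2, 1]),
                 se0 = unname(co[1, 2]), se1 = unname(co[2, 2]),
                 t_stat = unname(co[2, 3]), dof = dof,
                 p_value = unname(co[2, 4]),
                 random_structure = "none", bic = stats::BIC(fit),
                 n = nrow(table), converged = TRUE),
            class = "order_fit")
}

#' @export
print.order_fit <- function(x, ...) {
  cat(sprintf(
    "order fit [%s]: peak_time = %.4g %+.4g * train_time\n",
    x$random_structure, x$beta0, x$beta1))
  cat(sprintf("  slope t(%s) = %.3f, p = %.3g, BIC = %.1f\n",
              format(x$dof), x$t_stat, x$p_value, x$bic))
  invisible(x)
}

lmm_structures <- c("none", "subject_intercept", "trial_intercept",
                    "subject_and_trial_intercept",
                    "subject_intercept_and_slope")

lmm_formula <- function(structure) {
  switch(structure,
    none = NULL,
    subject_intercept = peak_time ~ train_time + (1 | subject),
    trial_intercept = peak_time ~ train_time + (1 | trial_id),
    subject_and_trial_intercept =
      peak_time ~ train_time + (1 | subject) + (1 | trial_id),
    subject_intercept_and_slope =
      peak_time ~ train_time + (1 + train_time | subject),
    stop("unknown random structure '", structure, "'"))
}

fit_one_lmm <- function(table, structure) {
  if (structure == "none") return(fit_order_lm(table))
  fml <- lmm_formula(structure)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = table, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)))),
    error = function(err) NULL)
  if (is.null(fit))
    return(structure(list(random_structure = structure, converged = FALSE,
                          bic = NA_real_),
                     class = "order_fit"))
  co <- summary(fit)$coefficients
  n <- nrow(table)
  dof <- n - nrow(co)
  tval <- unname(co["train_time", "t value"])
  structure(list(beta0 = unname(co[1, 1]), beta1 = unname(co[2, 1]),
                 se0 = unname(co[1, 2]), se1 = unname(co[2, 2]),
                 t_stat = tval, dof = dof,
                 p_value = 2 * stats::pt(-abs(tval), dof),
                 random_structure = structure, bic = stats::BIC(fit),
                 n = n, converged = TRUE),
            class = "order_fit")
}

#' Order inference by linear mixed models with BIC selection
#'
#' Fits the reactivation-time regression under several random-effect
#' structures (none; subject intercept; trial intercept; subject and trial
#' intercepts; subject intercept and slope), all by maximum likelihood so
#' their BICs are comparable, and selects the structure with the lowest BIC.
#' Random intercepts per subject and trial let the replay start at a
#' different moment in every trial and subject without biasing the slope.
#' Non-converging candidates are flagged and excluded, not fatal.
#'
#' @param table a `"reactivation_table"` with subject identifiers.
#' @param candidates character vector of random structures to try.
#' @return A list of class `"model_selection"`: `candidates` (list of
#'   `"order_fit"`), `winner` (index of the minimum-BIC converged candidate),
#'   `bic_table` (data.frame of structure, BIC, slope, p, converged).
#' @export
fit_order_lmm <- function(table, candidates = lmm_structures) {
  stopifnot(inherits(table, "reactivation_table"))
  candidates <- match.arg(candidates, lmm_structures, several.ok = TRUE)
  needs_subject <- grepl("subject", candidates)
  if (any(needs_subject) && length(unique(table$subject)) < 2L)
    stop("subject random effects require >= 2 subjects")
  df <- as.data.frame(table)
  df$trial_id <- interaction(df$subject, df$trial, drop = TRUE)
  df$subject <- factor(df$subject)
  cls <- class(table)
  fits <- lapply(candidates, function(s) {
    tab <- structure(df, class = cls)
    fit_one_lmm(tab, s)
  })
  bics <- vapply(fits, function(f) if (isTRUE(f$converged)) f$bic else NA_real_,
                 numeric(1))
  if (all(is.na(bics))) stop("no candidate mixed model converged")
  winner <- which.min(bics)
  bic_table <- data.frame(
    structure = candidates, bic = bics,
    beta1 = vapply(fits, function(f) f$beta1 %||% NA_real_, numeric(1)),
    p_value = vapply(fits, function(f) f$p_value %||% NA_real_, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  structure(list(candidates = fits, winner = winner, bic_table = bic_table),
            class = "model_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_selection <- function(x, ...) {
  cat("mixed-model selection (ML, lowest BIC wins):\n")
  print(x$bic_table, row.names = FALSE)
  cat("winner:", x$candidates[[x$winner]]$random_structure, "\n")
  invisible(x)
}

#' Subject-level order inference
#'
#' Averages reactivation times over trials within subject x training time
#' (removing the within-subject dependence that cross-validation induces
#' between trials), then fits subject-level mixed models (random intercept;
#' random intercept and slope) selected by BIC.
#'
#' @param table a `"reactivation_table"` with >= 3 subjects.
#' @return The winning `"order_fit"`, with the full `"model_selection"`
#'   attached as attribute `"selection"`.
#' @export
subject_level_fit <- function(table) {
  stopifnot(inherits(table, "reactivation_table"))
  if (length(unique(table$subject)) < 3L)
    stop("subject-level fit requires >= 3 subjects")
  agg <- stats::aggregate(peak_time ~ subject + train_time,
                          data = table, FUN = mean)
  agg$trial <- 1L
  tab <- structure(agg, train_times = sort(unique(agg$train_time)),
                   class = c("reactivation_table", "data.frame"))
  sel <- fit_order_lmm(tab, candidates = c("subject_intercept",
                                           "subject_intercept_and_slope"))
  out <- sel$candidates[[sel$winner]]
  attr(out, "selection") <- sel
  out
}

#' Shuffled-label null control
#'
#' Re-runs the decode-to-regression pipeline after permuting class labels
#' within each subject, which erases stimulus information while leaving the
#' temporal structure of the data untouched. The resulting fit is the null
#' against which the true order effect is judged.
#'
#' @param train,test paired `epochs` objects.
#' @param settings list of pipeline settings: `train_times` (or
#'   `train_window`), `test_window`, `k_folds`, `gamma`, `lowpass_hz`,
#'   `peak_window`.
#' @param seed integer seed for the permutation (and fold assignment).
#' @return An `"order_fit"` for the permuted-label pipeline, with the
#'   permuted-label `"reactivation_table"` attached as attribute `"table"`.
#' @export
shuffled_control <- function(train, test, settings, seed) {
  stopifnot(inherits(train, "epochs"), inherits(test, "epochs"))
  perm <- integer(n_trials(train))
  set.seed(seed)
  for (s in unique(train$subjects)) {
    idx <- which(train$subjects == s)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  train$labels <- train$labels[perm]
  test$labels <- test$labels[perm]
  tab <- reactivation_table_pipeline(train, test, settings,
                                     seed = sub_seed(seed, 1L))
  fit <- fit_order_lm(tab)
  attr(fit, "table") <- tab
  fit
}

# decode -> filter -> peak pipeline shared by the true and shuffled runs;
# decoding is run within each subject separately and tables are pooled
reactivation_table_pipeline <- function(train, test, settings, seed = 1L) {
  tts <- settings$train_times
  if (is.null(tts)) {
    w <- settings$train_window %||% range(train$times)
    tts <- train$times[window_indices(train$times, w)]
  }
  test_window <- settings$test_window %||% range(test$times)
  peak_window <- settings$peak_window %||% test_window
  tabs <- lapply(unique(train$subjects), function(s) {
    idx <- which(train$subjects == s)
    ev <- crossval_evidence(subset_trials(train, idx),
                            subset_trials(test, idx),
                            train_times = tts, test_window = test_window,
                            k_folds = settings$k_folds %||% 5L,
                            gamma = settings$gamma %||% 0.05,
                            seed = sub_seed(seed, match(s, unique(train$subjects))))
    tab <- build_table(ev, window = peak_window,
                       lowpass_hz = settings$lowpass_hz)
    tab$trial <- idx[tab$trial]
    tab
  })
  out <- do.call(rbind, tabs)
  structure(out, train_times = sort(unique(out$train_time)),
            window = attr(tabs[[1]], "window"),
            lowpass_hz = settings$lowpass_hz,
            class = c("reactivation_table", "data.frame"))
}
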