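# Per-subject leave-one-out cross-validation over the feature / classifier
# / window grid, plus the statistical comparison of classifiers (normality,
# Friedman, pairwise Wilcoxon signed-rank).

#' Make a classifier specification by name
#'
#' `"cdsrc"` maps to [cdsrc_params()]; `"svm"`, `"knn"`, `"lda"`, `"lr"`
#' map to [baseline_spec()].
#'
#' @param name Classifier name.
#' @param ... Parameter overrides.
#' @export
classifier_spec <- function(name, ...) {
  if (identical(name, "cdsrc")) {
    structure(list(name = "cdsrc", params = cdsrc_params(...)),
              class = "classifier_spec")
  } else if (name %in% c("svm", "knn", "lda", "lr")) {
    structure(list(name = name, params = baseline_spec(name, ...)),
              class = "classifier_spec")
  } else {
    stop("unknown classifier '", name,
         "'; expected one of cdsrc, svm, knn, lda, lr", call. = FALSE)
  }
}

# Train on one fold, predict held-out trials. Standardization is fitted on
# the training fold only. Routing: cdSRC scales columns without centering
# (centered balanced dictionaries are sign-symmetric and kill the residual
# cue); the SVM sees native-scale features because its fixed gamma = 1 is
# calibrated to the umol/L feature scale (z-scored 16-48-dim features make
# the RBF kernel collapse to the identity); KNN, LDA and LR get the full
# z-score.
fold_predict <- function(spec, train, test) {
  if (spec$name == "cdsrc") {
    st <- standardize_features(train, test, center = FALSE)
    model <- cdsrc_fit(st$train, spec$params)
    as.character(predict(model, st$test))
  } else if (spec$name == "svm") {
    as.character(fit_predict(spec$params, train, test))
  } else {
    st <- standardize_features(train, test)
    as.character(fit_predict(spec$params, st$train, st$test))
  }
}

#' Leave-one-out cross-validation for one subject
#'
#' One fold per trial: hold the trial out, fit on the remaining trials
#' (re-fitting the standardization on the fold's training set), predict,
#' and tally. Folds whose training set degenerates to a single class are
#' skipped and reported, never silently dropped.
#'
#' @param features A `trial_feature_set` (unstandardized; LOOCV
#'   standardizes per fold).
#' @param spec A [classifier_spec()].
#' @return List: `accuracy` (correct/total over evaluated folds),
#'   `predictions`, `truth`, `n_folds`, `skipped` (indices of skipped
#'   folds), `confusion` (table).
#' @export
loocv <- function(features, spec) {
  stopifnot(inherits(features, "trial_feature_set"),
            inherits(spec, "classifier_spec"))
  y <- features$y
  stopifnot(min(table(y)) >= 2)
  n <- length(y)
  preds <- rep(NA_character_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    tr <- subset_trials(features, setdiff(seq_len(n), i))
    if (length(unique(tr$y)) < 2) {
      skipped <- c(skipped, i)
      warning("LOOCV fold ", i, " skipped: single-class training set")
      next
    }
    te <- subset_trials(features, i)
    preds[i] <- fold_predict(spec, tr, te)
  }
  keep <- setdiff(seq_len(n), skipped)
  acc <- mean(preds[keep] == y[keep])
  list(accuracy = acc, predictions = preds, truth = y, n_folds = n,
       skipped = skipped,
       confusion = table(truth = y[keep], predicted = preds[keep]))
}

#' Summarize per-subject accuracies
#'
#' Arithmetic mean and sample standard deviation (denominator n - 1)
#' across subjects, per condition.
#'
#' @param cells Data frame with an `accuracy` column and any grouping
#'   columns (e.g. `classifier`, `features`, `window`).
#' @param by Character vector of grouping column names.
#' @return Data frame with `mean_accuracy`, `sd_accuracy`, `n_subjects`
#'   per group.
#' @export
summarize_accuracy <- function(cells, by = setdiff(names(cells),
                                                   c("subject", "accuracy"))) {
  stopifnot("accuracy" %in% names(cells))
  if (length(by) == 0) {
    return(data.frame(mean_accuracy = mean(cells$accuracy),
                      sd_accuracy = stats::sd(cells$accuracy),
                      n_subjects = nrow(cells)))
  }
  agg <- stats::aggregate(cells$accuracy, by = cells[by], FUN = mean)
  names(agg)[ncol(agg)] <- "mean_accuracy"
  agg$sd_accuracy <- stats::aggregate(cells$accuracy, by = cells[by],
                                      FUN = stats::sd)$x
  agg$n_subjects <- stats::aggregate(cells$accuracy, by = cells[by],
                                     FUN = length)$x
  agg
}

#' Statistical comparison of classifiers across subjects
#'
#' Given a subjects x classifiers accuracy matrix: Shapiro-Wilk normality
#' p per classifier, a Friedman test across classifiers, and two-sided
#' Wilcoxon signed-rank tests of the reference classifier against each of
#' the others (zero differences dropped; exact null when R's
#' implementation permits, normal approximation otherwise). Raw p values
#' are reported; Holm correction is available but off by default.
#'
#' @param acc Numeric matrix, rows = subjects, columns = classifiers
#'   (named). Must be complete.
#' @param reference Column name compared pairwise against the rest
#'   (default `"cdsrc"` if present, else the first column).
#' @param alpha Significance level flag threshold (default 0.05).
#' @param holm Apply Holm correction to the pairwise p values?
#' @return A `stats_report` list: `normality_p`, `friedman_stat`,
#'   `friedman_p`, `wilcoxon` (data.frame comparison/p/significant/note),
#'   `alpha`.
#' @export
compare_classifiers <- function(acc, reference = NULL, alpha = 0.05,
                                holm = FALSE) {
  stopifnot(is.matrix(acc), !anyNA(acc), ncol(acc) >= 2,
            !is.null(colnames(acc)))
  reference <- reference %||%
    (if ("cdsrc" %in% colnames(acc)) "cdsrc" else colnames(acc)[1])
  stopifnot(reference %in% colnames(acc))
  normality_p <- apply(acc, 2, function(v) {
    if (length(unique(v)) < 3) return(NA_real_)  # shapiro needs variation
    stats::shapiro.test(v)$p.value
  })
  fr <- stats::friedman.test(acc)
  fr_stat <- unname(fr$statistic)
  fr_p <- fr$p.value
  if (!is.finite(fr_stat)) {
    # every subject ranks all classifiers identically (all-tied rows):
    # no evidence of any difference
    fr_stat <- 0
    fr_p <- 1
  }
  others <- setdiff(colnames(acc), reference)
  wil <- lapply(others, function(cl) {
    d <- acc[, reference] - acc[, cl]
    if (all(d == 0)) {
      return(data.frame(comparison = paste(reference, "vs", cl),
                        p = NA_real_, significant = NA,
                        note = "undefined: all paired differences are zero"))
    }
    wt <- suppressWarnings(stats::wilcox.test(acc[, reference], acc[, cl],
                                              paired = TRUE))
    data.frame(comparison = paste(reference, "vs", cl), p = wt$p.value,
               significant = wt$p.value < alpha, note = "")
  })
  wil <- do.call(rbind, wil)
  if (holm) {
    ok <- !is.na(wil$p)
    wil$p[ok] <- stats::p.adjust(wil$p[ok], method = "holm")
    wil$significant[ok] <- wil$p[ok] < alpha
  }
  structure(list(normality_p = normality_p,
                 friedman_stat = fr_stat,
                 friedman_p = fr_p,
                 wilcoxon = wil, alpha = alpha,
                 reference = reference),
            class = "stats_report")
}
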