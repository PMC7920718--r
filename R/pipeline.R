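# End-to-end orchestration: synth -> MBLL -> preprocess -> features ->
# classify -> evaluate, driven by one flat config and one seed. Identical
# config + seed produce byte-identical report files.

#' Default run configuration
#'
#' One flat, JSON-serializable list controlling the whole pipeline. The
#' `"full"` scale mirrors the study grid (15 subjects, 2 sessions x 40
#' trials, 5 classifiers, 7 feature sets, 4 windows); `"smoke"` is a small
#' integration-sized run (3 subjects, 1 session x 20 trials, 2 classifiers,
#' 2 feature sets, 1 window).
#'
#' @param seed Master seed; per-subject seeds are derived from it by fixed
#'   offsets.
#' @param scale `"full"` or `"smoke"`.
#' @param ... Named overrides of any config field.
#' @export
default_config <- function(seed = 1, scale = c("full", "smoke"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    seed = seed,
    n_subjects = 15,
    n_sessions = 2,
    n_trials_per_session = 40,
    preset = "easy",
    synth = list(),                       # synth_config overrides
    filter = list(order = 1, low_hz = 0.02, high_hz = 0.1, zero_phase = TRUE),
    enable_cbsi = TRUE,
    baseline_mode = "linear",             # "linear" or "none"
    classifiers = c("cdsrc", "svm", "knn", "lda", "lr"),
    classifier_params = list(),
    features = c("M", "P", "R", "MP", "MR", "PR", "MPR"),
    windows = c("0-10", "2-8", "3-9", "4-10"),
    holm = FALSE
  )
  if (scale == "smoke") {
    cfg$n_subjects <- 3
    cfg$n_sessions <- 1
    cfg$n_trials_per_session <- 20
    cfg$classifiers <- c("cdsrc", "lda")
    # 20 trials -> 9 same-class trials in a LOOCV training fold; shrink the
    # cdOMP support so the dictionary minimum max(sparsity, K) still fits
    cfg$classifier_params <- list(cdsrc = list(sparsity = 5))
    cfg$features <- c("M", "MPR")
    cfg$windows <- "0-10"
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

parse_window <- function(w) {
  parts <- as.numeric(strsplit(w, "-")[[1]])
  window_spec(parts[1], parts[2])
}

validate_config <- function(config) {
  known <- c("cdsrc", "svm", "knn", "lda", "lr")
  bad <- setdiff(config$classifiers, known)
  if (length(bad) > 0) {
    stop("unknown classifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lapply(config$windows, parse_window)
  stopifnot(config$n_subjects >= 1)
  invisible(TRUE)
}

config_hash <- function(config) {
  fnv1a_hex(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

#' Run the full decoding pipeline
#'
#' For each subject: generate a synthetic recording (per-subject seed
#' derived from the master seed), convert optical density to HbO/HbR,
#' preprocess (band-pass -> CBSI -> baseline), extract features for every
#' window, and run LOOCV for every classifier x feature-set combination.
#' Summaries and (when at least 2 subjects and 2 classifiers are present)
#' the Friedman / Wilcoxon comparison are computed from the per-subject
#' cells. When `out_dir` is given, writes `accuracy_cells.csv`,
#' `accuracy_by_feature.csv`, `accuracy_by_window.csv`, `stats_tests.csv`
#' and `report.json`, each stamped with the config hash and package
#' version (no timestamps, so reruns are byte-identical).
#'
#' @param config A [default_config()] list.
#' @param out_dir Optional output directory.
#' @return List with `cells` (per subject/classifier/features/window
#'   accuracies), `summary`, `by_window`, `stats` (per window, or NULL),
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  hash <- config_hash(config)
  windows <- lapply(config$windows, parse_window)
  names(windows) <- config$windows
  specs <- lapply(config$classifiers, function(cl) {
    do.call(classifier_spec,
            c(list(name = cl), config$classifier_params[[cl]]))
  })
  names(specs) <- config$classifiers

  cells <- list()
  for (s in seq_len(config$n_subjects)) {
    scfg <- do.call(synth_config,
                    c(list(preset = config$preset), config$synth,
                      list(seed = derive_seed(config$seed, 100 + s))))
    od <- synth_subject(scfg, config$n_sessions, config$n_trials_per_session)
    hemo <- mbll_convert(od)
    hemo <- preprocess(hemo,
                       filter_spec(config$filter$order, config$filter$low_hz,
                                   config$filter$high_hz,
                                   config$filter$zero_phase),
                       enable_cbsi = config$enable_cbsi,
                       baseline = config$baseline_mode != "none")
    for (w in names(windows)) {
      full <- extract_features(hemo, windows[[w]], c("M", "P", "R"))
      for (fc in config$features) {
        fset <- restrict_codes(full, fc)
        for (cl in config$classifiers) {
          res <- loocv(fset, specs[[cl]])
          cells[[length(cells) + 1L]] <- data.frame(
            subject = s, classifier = cl, features = fc, window = w,
            accuracy = res$accuracy, n_trials = res$n_folds,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cells <- do.call(rbind, cells)

  summary_tab <- summarize_accuracy(cells, by = c("classifier", "features",
                                                  "window"))
  by_window <- summarize_accuracy(cells, by = c("classifier", "window"))

  stats_list <- NULL
  if (config$n_subjects >= 2 && length(config$classifiers) >= 2) {
    stats_list <- lapply(names(windows), function(w) {
      fc <- if ("MPR" %in% config$features) "MPR" else config$features[1]
      sub <- cells[cells$window == w & cells$features == fc, ]
      acc <- stats::xtabs(accuracy ~ subject + classifier, data = sub)
      acc <- matrix(acc, nrow = nrow(acc), dimnames = dimnames(acc))
      acc <- acc[, config$classifiers, drop = FALSE]
      compare_classifiers(acc, alpha = 0.05, holm = config$holm)
    })
    names(stats_list) <- names(windows)
  }

  out <- list(cells = cells, summary = summary_tab, by_window = by_window,
              stats = stats_list, config = config, config_hash = hash)
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

# Restrict a 3-code feature set to a code subset without re-extracting.
restrict_codes <- function(full, fc) {
  codes <- strsplit(fc, "")[[1]]
  keep <- grepl(paste0("_(", paste(codes, collapse = "|"), ")$"),
                colnames(full$X))
  full$X <- full$X[, keep, drop = FALSE]
  full$feature_names <- colnames(full$X)
  full$codes <- codes
  full
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) {
    df$config_hash <- result$config_hash
    df$package_version <- as.character(utils::packageVersion("nirsbci"))
    df
  }
  utils::write.csv(stamp(result$cells),
                   file.path(out_dir, "accuracy_cells.csv"), row.names = FALSE)
  utils::write.csv(stamp(result$summary),
                   file.path(out_dir, "accuracy_by_feature.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(result$by_window),
                   file.path(out_dir, "accuracy_by_window.csv"),
                   row.names = FALSE)
  if (!is.null(result$stats)) {
    st <- do.call(rbind, lapply(names(result$stats), function(w) {
      rep <- result$stats[[w]]
      df <- rep$wilcoxon
      df$window <- w
      df$friedman_stat <- rep$friedman_stat
      df$friedman_p <- rep$friedman_p
      df
    }))
    utils::write.csv(stamp(st), file.path(out_dir, "stats_tests.csv"),
                     row.names = FALSE)
  }
  report <- list(config = result$config, config_hash = result$config_hash,
                 package_version = as.character(utils::packageVersion("nirsbci")),
                 cells = result$cells, summary = result$summary)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(out_dir)
}
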