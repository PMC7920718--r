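# Plain-text readers/writers for the CSV subject layout:
#   <id>_od.csv      time_s, ch01_od760, ch01_od850, ..., ch16_od850
#   <id>_events.csv  kind, onset_s, duration_s, label
#   <id>_meta.json   sampling rate, wavelengths, config, seed

#' Write a synthetic subject to CSV
#'
#' Emits the optical-density CSV (one time column plus two wavelength
#' columns per channel), the events CSV, and a JSON sidecar with the
#' sampling rate, wavelengths and generator config.
#'
#' @param rec An `optical_recording`.
#' @param dir Output directory (created if missing).
#' @param id Subject identifier used as file prefix.
#' @return Invisibly, the three file paths.
#' @export
write_optical_csv <- function(rec, dir, id = "sub01") {
  stopifnot(inherits(rec, "optical_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(rec$od)[2]
  nch <- dim(rec$od)[1]
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate)
  wl <- rec$wavelengths %||% c(760, 850)
  for (ch in seq_len(nch)) {
    df[[sprintf("ch%02d_od%d", ch, wl[1])]] <- rec$od[ch, , 1]
    df[[sprintf("ch%02d_od%d", ch, wl[2])]] <- rec$od[ch, , 2]
  }
  f_od <- file.path(dir, paste0(id, "_od.csv"))
  f_ev <- file.path(dir, paste0(id, "_events.csv"))
  f_meta <- file.path(dir, paste0(id, "_meta.json"))
  utils::write.csv(df, f_od, row.names = FALSE)
  utils::write.csv(rec$schedule$events, f_ev, row.names = FALSE)
  meta <- list(sample_rate = rec$sample_rate, wavelengths = wl,
               channel_ids = rec$channel_ids,
               n_sessions = rec$schedule$n_sessions,
               n_trials_per_session = rec$schedule$n_trials_per_session,
               config = if (!is.null(rec$ground_truth))
                 unclass(rec$ground_truth$config) else NULL)
  jsonlite::write_json(meta, f_meta, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(c(od = f_od, events = f_ev, meta = f_meta))
}

#' Read a subject written by [write_optical_csv()]
#'
#' @param dir Directory containing the files.
#' @param id Subject identifier prefix.
#' @return An `optical_recording` (without ground truth).
#' @export
read_optical_csv <- function(dir, id = "sub01") {
  df <- utils::read.csv(file.path(dir, paste0(id, "_od.csv")))
  ev <- utils::read.csv(file.path(dir, paste0(id, "_events.csv")),
                        stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                              simplifyVector = TRUE)
  chcols <- grep("^ch[0-9]+_od", names(df), value = TRUE)
  nch <- length(chcols) / 2
  n <- nrow(df)
  od <- array(0, dim = c(nch, n, 2))
  wl <- meta$wavelengths
  for (ch in seq_len(nch)) {
    od[ch, , 1] <- df[[sprintf("ch%02d_od%d", ch, wl[1])]]
    od[ch, , 2] <- df[[sprintf("ch%02d_od%d", ch, wl[2])]]
  }
  sched <- structure(list(sample_rate = meta$sample_rate, events = ev,
                          n_sessions = meta$n_sessions,
                          n_trials_per_session = meta$n_trials_per_session),
                     class = "paradigm_schedule")
  structure(list(sample_rate = meta$sample_rate, wavelengths = wl, od = od,
                 channel_ids = meta$channel_ids, schedule = sched,
                 ground_truth = NULL),
            class = "optical_recording")
}

#' Write / read HbO-HbR concentration CSV
#'
#' Same channel column scheme as the optical layout, with `_hbo` / `_hbr`
#' suffixes; concentrations in umol/L.
#'
#' @param rec A `hemo_recording`.
#' @param path Output CSV path.
#' @export
write_hemo_csv <- function(rec, path) {
  stopifnot(inherits(rec, "hemo_recording"))
  n <- ncol(rec$hbo)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate)
  for (ch in seq_len(nrow(rec$hbo))) {
    df[[sprintf("ch%02d_hbo", ch)]] <- rec$hbo[ch, ]
    df[[sprintf("ch%02d_hbr", ch)]] <- rec$hbr[ch, ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a trial feature matrix as CSV (feature columns plus `label`)
#'
#' @param fset A `trial_feature_set`.
#' @param path Output CSV path.
#' @export
write_features_csv <- function(fset, path) {
  stopifnot(inherits(fset, "trial_feature_set"))
  df <- as.data.frame(fset$X)
  df$label <- fset$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
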