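# Preprocessing: first-order Butterworth band-pass (zero-phase by default),
# correlation-based signal improvement (CBSI) for motion artifacts, and
# baseline drift correction. Pipeline order is band-pass -> CBSI -> baseline.

#' Band-pass filter specification
#'
#' First-order Butterworth band-pass. Defaults: 0.02-0.1 Hz, zero-phase
#' (forward-backward, which squares the magnitude response). Only order 1
#' is supported; the pass band is chosen to reject respiration
#' (0.15-0.3 Hz), heartbeat (1.2-1.6 Hz) and Mayer waves (~0.1 Hz).
#'
#' @param order Filter order; must be 1.
#' @param low,high Band edges, Hz.
#' @param zero_phase Apply forward-backward (no phase shift)?
#' @export
filter_spec <- function(order = 1, low = 0.02, high = 0.1, zero_phase = TRUE) {
  if (order != 1) stop("only first-order Butterworth is supported", call. = FALSE)
  stopifnot(low > 0, low < high)
  structure(list(order = order, low = low, high = high,
                 zero_phase = zero_phase), class = "filter_spec")
}

# Digital coefficients of the first-order band-pass Butterworth: analog
# prototype 1/(s+1), band transform s -> (s^2 + w0^2)/(B s), bilinear
# transform with frequency prewarping. Matches scipy.signal.butter(1, ...).
butter_bandpass_coef <- function(low, high, fs) {
  K <- 2 * fs
  wl <- K * tan(pi * low / fs)
  wh <- K * tan(pi * high / fs)
  w0sq <- wl * wh
  B <- wh - wl
  a0 <- K^2 + B * K + w0sq
  list(b = c(B * K, 0, -B * K) / a0,
       a = c(1, 2 * (w0sq - K^2) / a0, (K^2 - B * K + w0sq) / a0))
}

# Direct-form IIR filtering, vectorized: 3-tap FIR numerator explicitly,
# recursive denominator via stats::filter (C speed).
iir_filter <- function(b, a, x) {
  n <- length(x)
  v <- b[1] * x +
    b[2] * c(0, x[-n]) +
    b[3] * c(0, 0, x[seq_len(max(0, n - 2))])
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

# Zero-phase filtering with odd-reflect padding. The transient of the
# 0.02 Hz edge decays over ~fs/low samples; pad 3x that (clipped to n - 1).
filtfilt_reflect <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  y <- rev(iir_filter(b, a, rev(iir_filter(b, a, ext))))
  y[(padlen + 1):(padlen + n)]
}

#' Band-pass filter a hemodynamic recording
#'
#' Applies the first-order Butterworth band-pass identically to every HbO
#' and HbR channel. With `zero_phase = TRUE` (default) the filter is run
#' forward and backward so features stay time-locked to task onsets; the
#' magnitude response is then the square of the single-pass response.
#'
#' @param rec A `hemo_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `hemo_recording`.
#' @export
nirs_bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "hemo_recording"))
  fs <- rec$sample_rate
  if (spec$high >= fs / 2) {
    stop("band edge ", spec$high, " Hz is at or above Nyquist (",
         fs / 2, " Hz)", call. = FALSE)
  }
  cf <- butter_bandpass_coef(spec$low, spec$high, fs)
  padlen <- as.integer(ceiling(3 * fs / spec$low))
  apply_one <- function(x) {
    if (spec$zero_phase) filtfilt_reflect(cf$b, cf$a, x, padlen)
    else iir_filter(cf$b, cf$a, x)
  }
  rec$hbo <- t(apply(rec$hbo, 1, apply_one))
  rec$hbr <- t(apply(rec$hbr, 1, apply_one))
  rec
}

#' Correlation-based signal improvement (CBSI) motion-artifact correction
#'
#' Per channel, with `alpha = sd(hbo)/sd(hbr)`:
#' `hbo' = (hbo - alpha * hbr)/2`, `hbr' = -hbo'/alpha`. The corrected HbO
#' and HbR are exactly anti-correlated (Pearson r = -1), and any artifact
#' added with equal amplitude and sign to both signals (the typical motion
#' signature) is cancelled when `alpha = 1`. Channels with zero-variance
#' HbR pass through unchanged with a warning.
#'
#' @param rec A `hemo_recording`.
#' @return The corrected `hemo_recording`.
#' @export
cbsi_correct <- function(rec) {
  stopifnot(inherits(rec, "hemo_recording"))
  for (ch in seq_len(nrow(rec$hbo))) {
    s_r <- stats::sd(rec$hbr[ch, ])
    if (s_r == 0) {
      warning("CBSI: channel ", ch,
              " has zero-variance HbR; passed through unchanged")
      next
    }
    alpha <- stats::sd(rec$hbo[ch, ]) / s_r
    hbo2 <- (rec$hbo[ch, ] - alpha * rec$hbr[ch, ]) / 2
    rec$hbo[ch, ] <- hbo2
    rec$hbr[ch, ] <- -hbo2 / alpha
  }
  rec
}

#' Baseline drift correction
#'
#' Per channel: subtract the least-squares line fitted over the whole
#' recording (removing linear drift), then subtract the mean over the
#' schedule's baseline segment(s) so the baseline period averages zero.
#' If the schedule has no baseline event the whole-recording mean is used
#' instead, with a warning.
#'
#' @param rec A `hemo_recording` whose schedule contains the baseline event.
#' @return The corrected `hemo_recording`.
#' @export
baseline_correct <- function(rec) {
  stopifnot(inherits(rec, "hemo_recording"))
  n <- ncol(rec$hbo)
  fs <- rec$sample_rate
  t <- (seq_len(n) - 1) / fs
  tc <- t - mean(t)
  ss <- sum(tc^2)
  ev <- rec$schedule$events
  base <- ev[ev$kind == "baseline", , drop = FALSE]
  if (nrow(base) == 0) {
    warning("no baseline event in schedule; using whole-recording mean")
    bidx <- seq_len(n)
  } else {
    bidx <- unlist(lapply(seq_len(nrow(base)), function(i) {
      i0 <- as.integer(round(base$onset_s[i] * fs)) + 1L
      i1 <- min(n, i0 + as.integer(floor(base$duration_s[i] * fs)) - 1L)
      i0:i1
    }))
  }
  detrend <- function(x) {
    slope <- sum(tc * x) / ss
    x <- x - mean(x) - slope * tc
    x - mean(x[bidx])
  }
  rec$hbo <- t(apply(rec$hbo, 1, detrend))
  rec$hbr <- t(apply(rec$hbr, 1, detrend))
  rec
}

#' Full preprocessing pipeline
#'
#' Runs band-pass -> CBSI -> baseline correction in that fixed order.
#'
#' @param rec A `hemo_recording`.
#' @param spec A [filter_spec()].
#' @param enable_cbsi Apply CBSI? (default TRUE)
#' @param baseline Apply baseline drift correction? (default TRUE)
#' @return The preprocessed `hemo_recording`.
#' @export
preprocess <- function(rec, spec = filter_spec(), enable_cbsi = TRUE,
                       baseline = TRUE) {
  rec <- nirs_bandpass(rec, spec)
  if (enable_cbsi) rec <- cbsi_correct(rec)
  if (baseline) rec <- baseline_correct(rec)
  rec
}
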