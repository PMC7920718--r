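# Synthetic dual-wavelength fNIRS generator with known hemodynamic ground
# truth: double-gamma event responses on motor channels, physiological
# oscillations (cardiac / respiration / Mayer), drift, white noise and
# motion spikes, inverted through the Beer-Lambert forward map to optical
# density.

#' Synthetic-data configuration
#'
#' Parameters of the synthetic fNIRS world. The `"easy"` preset gives a
#' clearly decodable dataset whose HbO excursions stay within roughly
#' -0.01..0.08 umol/L; the `"null"` preset has zero class separation
#' (activation amplitude exactly 0) and identical noise.
#'
#' @param preset `"easy"` or `"null"`.
#' @param ... Named overrides of any field below.
#' @return A `synth_config` list with fields:
#' \describe{
#'   \item{hrf_lag, hrf_peak, hrf_undershoot, hrf_ratio}{double-gamma HRF:
#'     neural-to-hemodynamic lag (s), rise-to-peak (s), undershoot mode (s),
#'     undershoot/peak ratio.}
#'   \item{amp_walk, amp_sd}{mean and sd (umol/L) of the per-trial HbO
#'     response amplitude for walk trials; idle trials add nothing.}
#'   \item{hbr_ratio}{HbR truth = -hbr_ratio * HbO truth.}
#'   \item{channel_gain_range}{per-channel activation gain, drawn once per
#'     subject uniformly in this range.}
#'   \item{noise_cardiac, noise_resp, noise_mayer}{sinusoid amplitudes
#'     (umol/L) in the 1.2-1.6, 0.15-0.3 and ~0.1 Hz bands.}
#'   \item{band_cardiac, band_resp, band_mayer}{the frequency bands (Hz).}
#'   \item{noise_white}{white-noise sd, umol/L.}
#'   \item{drift_slope_range}{linear drift slope range, umol/L per second.}
#'   \item{drift_walk_sd}{random-walk drift step sd, umol/L per sample.}
#'   \item{spike_rate, spike_amp, spike_tau}{motion artifacts: events/min,
#'     amplitude scale (umol/L), exponential decay constant (s).}
#'   \item{hbr_noise_scale}{physiological/white/drift noise amplitude on HbR
#'     relative to HbO.}
#'   \item{seed}{integer; fixes the whole dataset bit-for-bit.}
#' }
#' @export
synth_config <- function(preset = c("easy", "null"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    hrf_lag = 2, hrf_peak = 5, hrf_undershoot = 15, hrf_ratio = 1 / 6,
    amp_walk = 0.06, amp_sd = 0.01,
    hbr_ratio = 1 / 3,
    channel_gain_range = c(0.6, 1),
    noise_cardiac = 0.02, band_cardiac = c(1.2, 1.6),
    noise_resp = 0.015,  band_resp = c(0.15, 0.3),
    noise_mayer = 0.02,  band_mayer = c(0.08, 0.12),
    noise_white = 0.005,
    drift_slope_range = c(-2e-5, 2e-5),
    drift_walk_sd = 2e-4,
    spike_rate = 0.5, spike_amp = 0.1, spike_tau = 1.5,
    hbr_noise_scale = 0.5,
    seed = 1
  )
  if (preset == "null") {
    cfg$amp_walk <- 0
    cfg$amp_sd <- 0
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown synth_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  amps <- c(cfg$amp_walk, cfg$amp_sd, cfg$noise_cardiac, cfg$noise_resp,
            cfg$noise_mayer, cfg$noise_white, cfg$drift_walk_sd,
            cfg$spike_rate, cfg$spike_amp)
  stopifnot(all(amps >= 0))
  structure(c(cfg, list(preset = preset)), class = "synth_config")
}

#' Double-gamma hemodynamic response function
#'
#' `h(t) = g(t - lag; peak) - ratio * g(t - lag; undershoot)` where `g` is a
#' unit-scale gamma density with the given mode; zero for `t < lag`.
#' Returned values are normalized so the positive peak equals 1 on the
#' evaluated grid.
#'
#' @param t Time grid, s.
#' @param lag,peak,undershoot,ratio HRF shape parameters (see
#'   [synth_config()]).
#' @return Numeric vector, unit positive peak.
#' @export
hrf_double_gamma <- function(t, lag = 2, peak = 5, undershoot = 15,
                             ratio = 1 / 6) {
  tt <- t - lag
  h <- ifelse(tt > 0,
              stats::dgamma(tt, shape = peak + 1, rate = 1) -
                ratio * stats::dgamma(tt, shape = undershoot + 1, rate = 1),
              0)
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

default_channel_ids <- function() {
  sprintf("ch%02d_%s", 1:16, rep(c("L", "R"), each = 8))
}

#' Generate the noise-free hemodynamic ground truth for a schedule
#'
#' Each walk task event adds `amplitude * gain[channel]` times a unit-peak
#' double-gamma response starting at the task onset (peak ~7 s after onset
#' with the defaults: 2 s lag + 5 s rise); idle events add nothing. HbR is
#' `-hbr_ratio` times HbO. Per-trial amplitudes are drawn from
#' `N(amp_walk, amp_sd)` truncated at 0; per-channel gains uniformly from
#' `channel_gain_range`. Fully determined by `config$seed`.
#'
#' @param schedule A [build_schedule()] result.
#' @param config A [synth_config()].
#' @return A `hemo_recording` whose `ground_truth` records trial labels,
#'   per-trial amplitudes and per-channel gains.
#' @export
generate_hemo_truth <- function(schedule, config = synth_config()) {
  validate_schedule(schedule)
  fs <- schedule$sample_rate
  n <- n_samples(schedule)
  nch <- 16L
  tasks <- task_events(schedule)
  with_seed(derive_seed(config$seed, 1), {
    gains <- stats::runif(nch, config$channel_gain_range[1],
                          config$channel_gain_range[2])
    amps <- numeric(nrow(tasks))
    walk <- tasks$label == "walk"
    if (config$amp_walk == 0 && config$amp_sd == 0) {
      amps[walk] <- 0
    } else {
      amps[walk] <- pmax(0, stats::rnorm(sum(walk), config$amp_walk,
                                         config$amp_sd))
    }
    hrf_len <- as.integer(30 * fs)
    hrf <- hrf_double_gamma(seq(0, by = 1 / fs, length.out = hrf_len),
                            config$hrf_lag, config$hrf_peak,
                            config$hrf_undershoot, config$hrf_ratio)
    resp <- numeric(n)
    for (i in seq_len(nrow(tasks))) {
      if (!walk[i] || amps[i] == 0) next
      i0 <- as.integer(round(tasks$onset_s[i] * fs)) + 1L
      idx <- i0:min(n, i0 + hrf_len - 1L)
      resp[idx] <- resp[idx] + amps[i] * hrf[seq_along(idx)]
    }
    hbo <- outer(gains, resp)
  })
  hbr <- -config$hbr_ratio * hbo
  structure(list(sample_rate = fs, hbo = hbo, hbr = hbr,
                 channel_ids = default_channel_ids(),
                 schedule = schedule,
                 ground_truth = list(labels = tasks$label,
                                     amplitudes = amps,
                                     channel_gains = gains,
                                     config = config)),
            class = "hemo_recording")
}

# One channel's structured noise (physiological sinusoids + drift + white).
channel_noise <- function(n, fs, config) {
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  for (band in c("cardiac", "resp", "mayer")) {
    amp <- config[[paste0("noise_", band)]]
    if (amp <= 0) next
    b <- config[[paste0("band_", band)]]
    f <- stats::runif(1, b[1], b[2])
    phi <- stats::runif(1, 0, 2 * pi)
    out <- out + amp * sin(2 * pi * f * t + phi)
  }
  slope <- stats::runif(1, config$drift_slope_range[1],
                        config$drift_slope_range[2])
  out <- out + slope * t
  if (config$drift_walk_sd > 0) {
    out <- out + cumsum(stats::rnorm(n, 0, config$drift_walk_sd))
  }
  if (config$noise_white > 0) {
    out <- out + stats::rnorm(n, 0, config$noise_white)
  }
  out
}

# Sparse exponentially-decaying transients, added with the SAME sign to HbO
# and HbR so that their correlation is positive -- the signature CBSI removes.
channel_spikes <- function(n, fs, config) {
  out <- numeric(n)
  dur_min <- n / fs / 60
  k <- stats::rpois(1, config$spike_rate * dur_min)
  if (k == 0) return(out)
  kern_len <- as.integer(ceiling(5 * config$spike_tau * fs))
  kern <- exp(-(seq_len(kern_len) - 1) / (config$spike_tau * fs))
  for (i in seq_len(k)) {
    i0 <- sample.int(n, 1)
    a <- config$spike_amp * stats::runif(1, 0.5, 1.5) *
      sample(c(-1, 1), 1)
    idx <- i0:min(n, i0 + kern_len - 1L)
    out[idx] <- out[idx] + a * kern[seq_along(idx)]
  }
  out
}

#' Add noise to a hemodynamic truth and invert to optical density
#'
#' Adds, per channel: sinusoids with channel-specific random frequency and
#' phase in the cardiac, respiration and Mayer bands; linear plus
#' random-walk drift; white noise; and sparse motion spikes shared (same
#' sign) between HbO and HbR. The noisy concentrations are then mapped to
#' dual-wavelength optical density by the exact Beer-Lambert forward map,
#' so [mbll_convert()] recovers them to machine precision.
#'
#' @param truth A [generate_hemo_truth()] result.
#' @param config The [synth_config()] used for the truth.
#' @param table An [extinction_table()].
#' @return An `optical_recording` with the ground truth carried along.
#' @export
add_noise_and_invert <- function(truth, config = synth_config(),
                                 table = extinction_table()) {
  stopifnot(inherits(truth, "hemo_recording"))
  fs <- truth$sample_rate
  n <- ncol(truth$hbo)
  nch <- nrow(truth$hbo)
  hbo <- truth$hbo
  hbr <- truth$hbr
  with_seed(derive_seed(config$seed, 2), {
    for (ch in seq_len(nch)) {
      hbo[ch, ] <- hbo[ch, ] + channel_noise(n, fs, config)
      hbr[ch, ] <- hbr[ch, ] + config$hbr_noise_scale * channel_noise(n, fs, config)
      sp <- channel_spikes(n, fs, config)
      hbo[ch, ] <- hbo[ch, ] + sp
      hbr[ch, ] <- hbr[ch, ] + sp
    }
  })
  noisy <- structure(list(sample_rate = fs, hbo = hbo, hbr = hbr,
                          channel_ids = truth$channel_ids,
                          schedule = truth$schedule,
                          ground_truth = truth$ground_truth),
                     class = "hemo_recording")
  mbll_forward(noisy, table)
}

#' Generate one synthetic subject
#'
#' Convenience wrapper: [build_schedule()] + [generate_hemo_truth()] +
#' [add_noise_and_invert()], all seeded from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param n_sessions,n_trials_per_session Passed to [build_schedule()].
#' @return An `optical_recording`.
#' @export
synth_subject <- function(config = synth_config(), n_sessions = 2,
                          n_trials_per_session = 40) {
  sched <- build_schedule(n_sessions, n_trials_per_session,
                          seed = derive_seed(config$seed, 0))
  truth <- generate_hemo_truth(sched, config)
  add_noise_and_invert(truth, config)
}
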