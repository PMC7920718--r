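# Paradigm schedule: block design of a walking-imagery / idle-state session.
#
# One session is 60 s baseline, then n trials of (2 s cue + 10 s task +
# 30 s rest), then 180 s eyes-closed rest: 60 + 42*n + 180 seconds.

.SEG <- list(baseline = 60, cue = 2, task = 10, rest = 30, final_rest = 180)

#' Build a walking-imagery experimental schedule
#'
#' Constructs the block-design event schedule used throughout the package:
#' per session, a 60 s baseline, `n_trials_per_session` trials of
#' 2 s cue + 10 s task + 30 s rest, and a final 180 s rest. Trial classes
#' (`walk` / `idle`) are exactly balanced over all sessions and their order
#' is a seeded uniform permutation.
#'
#' @param n_sessions Number of sessions (default 2).
#' @param n_trials_per_session Trials per session (default 40).
#' @param seed Integer seed fixing the class order.
#' @param sample_rate Sampling rate in Hz (default 20).
#' @return A `paradigm_schedule`: list with `sample_rate`, `events`
#'   (data.frame of kind, onset_s, duration_s, label), `n_sessions`,
#'   `n_trials_per_session`.
#' @examples
#' sched <- build_schedule(1, 40, seed = 1)
#' schedule_duration(sched)  # 1860 s
#' @export
build_schedule <- function(n_sessions = 2, n_trials_per_session = 40,
                           seed = 1, sample_rate = 20) {
  stopifnot(n_sessions >= 1, n_trials_per_session >= 1)
  n_total <- n_sessions * n_trials_per_session
  if (n_total %% 2L != 0L) {
    stop("total trial count (", n_total,
         ") is odd: walk/idle classes cannot be balanced", call. = FALSE)
  }
  labels <- with_seed(seed, sample(rep(c("walk", "idle"), n_total / 2L)))

  kind <- character(0); onset <- numeric(0); dur <- numeric(0); lab <- character(0)
  t <- 0; k <- 0L
  for (s in seq_len(n_sessions)) {
    kind <- c(kind, "baseline"); onset <- c(onset, t)
    dur <- c(dur, .SEG$baseline); lab <- c(lab, "none")
    t <- t + .SEG$baseline
    for (i in seq_len(n_trials_per_session)) {
      k <- k + 1L
      kind <- c(kind, "cue", "task", "rest")
      onset <- c(onset, t, t + .SEG$cue, t + .SEG$cue + .SEG$task)
      dur <- c(dur, .SEG$cue, .SEG$task, .SEG$rest)
      lab <- c(lab, labels[k], labels[k], "none")
      t <- t + .SEG$cue + .SEG$task + .SEG$rest
    }
    kind <- c(kind, "final_rest"); onset <- c(onset, t)
    dur <- c(dur, .SEG$final_rest); lab <- c(lab, "none")
    t <- t + .SEG$final_rest
  }
  structure(list(
    sample_rate = sample_rate,
    events = data.frame(kind = kind, onset_s = onset, duration_s = dur,
                        label = lab, stringsAsFactors = FALSE),
    n_sessions = n_sessions,
    n_trials_per_session = n_trials_per_session
  ), class = "paradigm_schedule")
}

#' Total schedule duration in seconds
#' @param schedule A `paradigm_schedule`.
#' @export
schedule_duration <- function(schedule) {
  ev <- schedule$events
  ev$onset_s[nrow(ev)] + ev$duration_s[nrow(ev)]
}

#' Task events of a schedule
#' @param schedule A `paradigm_schedule`.
#' @return The `task` rows of the event table (one per trial, in time order).
#' @export
task_events <- function(schedule) {
  schedule$events[schedule$events$kind == "task", , drop = FALSE]
}

# Number of samples covering the schedule: floor(duration * rate), the
# rounding convention shared by every module.
n_samples <- function(schedule) {
  as.integer(floor(schedule_duration(schedule) * schedule$sample_rate))
}

#' Check schedule invariants
#'
#' Verifies contiguity, ordering, cue/task/rest structure, per-session
#' baseline and final rest, and exact class balance. Errors on violation.
#' @param schedule A `paradigm_schedule`.
#' @return Invisibly `TRUE`.
#' @export
validate_schedule <- function(schedule) {
  ev <- schedule$events
  stopifnot(all(diff(ev$onset_s) > 0))
  # contiguous, non-overlapping
  stopifnot(all(abs(ev$onset_s[-1] - (ev$onset_s[-nrow(ev)] +
                                        ev$duration_s[-nrow(ev)])) < 1e-9))
  it <- which(ev$kind == "task")
  stopifnot(all(ev$kind[it - 1L] == "cue"), all(ev$duration_s[it - 1L] == .SEG$cue),
            all(ev$kind[it + 1L] == "rest"), all(ev$duration_s[it + 1L] == .SEG$rest))
  stopifnot(sum(ev$kind == "baseline") == schedule$n_sessions,
            sum(ev$kind == "final_rest") == schedule$n_sessions,
            length(it) == schedule$n_sessions * schedule$n_trials_per_session)
  labs <- ev$label[it]
  stopifnot(sum(labs == "walk") == sum(labs == "idle"))
  invisible(TRUE)
}
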