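# Behavioral indices: sucrose preference, tone-locked freezing-epoch
# quantification, and motion-index epoch summaries.

#' Sucrose preference index
#'
#' S_I = (s - w) / (s + w) for sucrose volume s and water volume w consumed
#' over 24 h; in [-1, 1], with positive values indicating sucrose preference
#' and a drop suggesting anhedonia.
#'
#' @param s sucrose volume (mL, >= 0); vectorized.
#' @param w water volume (mL, >= 0); vectorized.
#' @return preference index per subject; NA with a warning where s + w = 0.
#' @export
sucrose_index <- function(s, w) {
  if (any(s < 0 | w < 0)) stop("volumes must be nonnegative", call. = FALSE)
  tot <- s + w
  out <- ifelse(tot > 0, (s - w) / tot, NA_real_)
  if (anyNA(out)) {
    warning("undefined preference index where total intake is 0",
            call. = FALSE)
  }
  out
}

#' Fear-conditioning session layout
#'
#' Defaults describe the standard cued protocol: 180 s baseline, four 20 s
#' tones separated by 190 s inter-trial intervals, a shock in the tone's
#' final second on day 1, scored over a 60 s epoch per trial (20 s pre-shock
#' tone + 40 s post-shock). Video at 30 fps with a 30-frame (1 s) minimum
#' freezing bout.
#'
#' @param baseline_s baseline before the first tone (s).
#' @param tone_dur_s tone duration (s).
#' @param iti_s interval between tone offsets and the next onset (s).
#' @param n_trials tone presentations per session.
#' @param pre_shock_s scored tone interval before the shock (s).
#' @param post_shock_s scored interval after the shock (s).
#' @param fps video frame rate.
#' @param min_freeze_frames minimum bout duration in frames.
#' @return object of class `fear_session_spec`.
#' @export
fear_session_spec <- function(baseline_s = 180, tone_dur_s = 20, iti_s = 190,
                              n_trials = 4, pre_shock_s = 20,
                              post_shock_s = 40, fps = 30,
                              min_freeze_frames = 30) {
  spec <- list(baseline_s = baseline_s, tone_dur_s = tone_dur_s,
               iti_s = iti_s, n_trials = n_trials,
               pre_shock_s = pre_shock_s, post_shock_s = post_shock_s,
               fps = fps, min_freeze_frames = min_freeze_frames)
  if (pre_shock_s + post_shock_s != 60) {
    warning("scored epoch is not the standard 60 s", call. = FALSE)
  }
  structure(spec, class = "fear_session_spec")
}

#' Scoring windows for each tone-shock trial
#'
#' One window per trial, starting at the tone onset and lasting
#' pre_shock_s + post_shock_s (60 s by default). Tone onsets fall at
#' baseline + (i - 1) * (tone_dur + iti).
#'
#' @param spec a `fear_session_spec`.
#' @return data.frame with trial, start_s, end_s (end exclusive).
#' @export
epoch_windows <- function(spec = fear_session_spec()) {
  stopifnot(inherits(spec, "fear_session_spec"))
  onset <- spec$baseline_s +
    (seq_len(spec$n_trials) - 1) * (spec$tone_dur_s + spec$iti_s)
  len <- spec$pre_shock_s + spec$post_shock_s
  data.frame(trial = seq_len(spec$n_trials),
             start_s = onset, end_s = onset + len)
}

validate_freeze_events <- function(events, spec) {
  if (nrow(events) == 0) return(invisible(events))
  if (any(events$end_s <= events$start_s)) {
    stop("freezing bouts must have positive duration", call. = FALSE)
  }
  min_dur <- spec$min_freeze_frames / spec$fps
  if (any(events$end_s - events$start_s < min_dur - 1e-9)) {
    stop("bouts shorter than the minimum freeze duration (",
         min_dur, " s)", call. = FALSE)
  }
  ord <- order(events$start_s)
  if (is.unsorted(events$start_s)) {
    stop("bouts must be ordered by start time", call. = FALSE)
  }
  if (nrow(events) > 1 &&
      any(events$start_s[-1] < events$end_s[-nrow(events)])) {
    stop("bouts must not overlap", call. = FALSE)
  }
  invisible(events)
}

#' Per-trial freezing counts and percent time
#'
#' A bout is counted in a trial window when its start time falls inside the
#' window; bouts spanning a window edge have their scored duration clipped
#' at the window. The daily total sums the per-trial counts. Percent time is
#' the summed within-window bout overlap divided by the window length, and
#' is reported as the companion measure.
#'
#' @param events data.frame of freezing bouts with columns start_s, end_s
#'   (non-overlapping, ordered, each >= the minimum bout duration).
#' @param spec a `fear_session_spec`.
#' @return list with `per_trial` (trial, count, percent_time) and
#'   `daily_total` (summed counts).
#' @export
freezing_counts <- function(events, spec = fear_session_spec()) {
  stopifnot(inherits(spec, "fear_session_spec"))
  events <- as.data.frame(events)
  if (nrow(events)) validate_freeze_events(events, spec)
  win <- epoch_windows(spec)
  len <- spec$pre_shock_s + spec$post_shock_s
  count <- integer(nrow(win))
  pct <- numeric(nrow(win))
  for (t in seq_len(nrow(win))) {
    a <- win$start_s[t]; b <- win$end_s[t]
    if (nrow(events)) {
      count[t] <- sum(events$start_s >= a & events$start_s < b)
      ov <- pmin(events$end_s, b) - pmax(events$start_s, a)
      pct[t] <- sum(pmax(ov, 0)) / len
    }
  }
  list(per_trial = data.frame(trial = win$trial, count = count,
                              percent_time = pct),
       daily_total = sum(count))
}

#' Mean motion index per scoring epoch
#'
#' Averages motion-index samples falling inside each 60 s trial window;
#' epochs with no samples are NA and flagged.
#'
#' @param samples data.frame with columns time_s (sorted ascending) and
#'   motion_au.
#' @param spec a `fear_session_spec`.
#' @return data.frame with trial, mean_motion, n_samples.
#' @export
motion_epoch_summary <- function(samples, spec = fear_session_spec()) {
  samples <- as.data.frame(samples)
  if (is.unsorted(samples$time_s)) {
    stop("motion samples must be sorted by time", call. = FALSE)
  }
  win <- epoch_windows(spec)
  out <- data.frame(trial = win$trial, mean_motion = NA_real_,
                    n_samples = 0L)
  for (t in seq_len(nrow(win))) {
    inw <- samples$time_s >= win$start_s[t] & samples$time_s < win$end_s[t]
    out$n_samples[t] <- sum(inw)
    if (any(inw)) out$mean_motion[t] <- mean(samples$motion_au[inw])
  }
  if (anyNA(out$mean_motion)) {
    warning("epoch(s) with no motion samples: ",
            paste(out$trial[is.na(out$mean_motion)], collapse = ", "),
            call. = FALSE)
  }
  out
}
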