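# Sliding-window segmentation of the acceleration norm and annotation-driven
# window labeling. Windows are 3 s with 1 s shared between adjacent windows
# (step = 2 s); only complete windows are emitted. Indices are 0-based
# half-open.

#' Sliding-window start/end indices
#'
#' Windows of `window_s` seconds whose starts advance by
#' `window_s - overlap_s` so adjacent windows share `overlap_s` seconds.
#' Only full-length windows are returned: for `n` samples the count is
#' `floor((n - w) / s) + 1` when `n >= w` (w = window samples, s = step
#' samples), otherwise 0.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 3).
#' @param overlap_s Overlap between adjacent windows in seconds (default 1).
#' @return Integer matrix with columns `start` (0-based inclusive) and
#'   `end` (exclusive), one row per window.
#' @export
sliding_windows <- function(n, fs = 100, window_s = 3, overlap_s = 1) {
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (overlap_s <= 0 || overlap_s >= window_s) {
    stop("`overlap_s` must lie strictly between 0 and `window_s`",
         call. = FALSE)
  }
  w <- round(window_s * fs)
  s <- round((window_s - overlap_s) * fs)
  if (n < w) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  }
  starts <- seq.int(0L, n - w, by = s)
  cbind(start = starts, end = starts + w)
}

#' Resolve a window's ground-truth label
#'
#' Maximum-overlap rule: among non-error annotation events, the event class
#' covering the most samples of the window wins; `light` and `daily_care`
#' both map to `non_aggressive`, giving the binary classification target.
#' A window with less than half its samples inside any event is
#' `unlabeled`. Ties between aggressive and non-aggressive coverage break
#' toward `non_aggressive`.
#'
#' @param window Length-2 numeric (start index, end index), 0-based
#'   half-open, or one row of [sliding_windows()].
#' @param events An `annotation_events` data.frame.
#' @param fs Sampling rate in Hz.
#' @return One of `"aggressive"`, `"non_aggressive"`, `"unlabeled"`.
#' @export
label_window <- function(window, events, fs = 100) {
  start_s <- window[1] / fs
  end_s <- window[2] / fs
  ev <- events[!events$error_flag, , drop = FALSE]
  if (nrow(ev) == 0L) return("unlabeled")
  cover <- pmax(0, pmin(ev$end_s, end_s) - pmax(ev$start_s, start_s))
  agg <- sum(cover[ev$label == "aggressive"])
  non <- sum(cover[ev$label != "aggressive"])
  if (max(agg, non) < (end_s - start_s) / 2) return("unlabeled")
  if (agg > non) "aggressive" else "non_aggressive"
}

#' Segment one recording
#'
#' Computes the acceleration norm, applies [sliding_windows()], and labels
#' each window against the recording's annotation events.
#'
#' @param rec An `imu_recording`.
#' @param events An `annotation_events` data.frame.
#' @param window_s,overlap_s Window geometry in seconds.
#' @return List of segments; each has `recording_id`, `position`,
#'   `start_idx`, `end_idx`, `norm`, `label`.
#' @export
segment_recording <- function(rec, events, window_s = 3, overlap_s = 1) {
  norm <- acceleration_norm(rec$ax, rec$ay, rec$az)
  win <- sliding_windows(length(norm), rec$fs, window_s, overlap_s)
  lapply(seq_len(nrow(win)), function(i) {
    s <- win[i, 1]
    e <- win[i, 2]
    list(recording_id = rec$recording_id, position = rec$position,
         start_idx = s, end_idx = e,
         norm = norm[(s + 1L):e],
         label = label_window(c(s, e), events, rec$fs))
  })
}

#' Segment an entire session
#'
#' Runs [segment_recording()] over every entry and groups the resulting
#' segments by sensor position. Unlabeled windows are dropped from the
#' modeling set; their count is reported via the `n_unlabeled` attribute.
#'
#' @param session An `imu_session`.
#' @param window_s,overlap_s Window geometry in seconds.
#' @return Named list (one element per position present) of segment lists,
#'   with attribute `n_unlabeled`.
#' @export
segment_session <- function(session, window_s = 3, overlap_s = 1) {
  segs <- list()
  n_unlabeled <- 0L
  for (entry in session$entries) {
    ss <- segment_recording(entry$recording, entry$events, window_s, overlap_s)
    keep <- vapply(ss, function(s) s$label != "unlabeled", logical(1))
    n_unlabeled <- n_unlabeled + sum(!keep)
    pos <- entry$recording$position
    segs[[pos]] <- c(segs[[pos]], ss[keep])
  }
  attr(segs, "n_unlabeled") <- n_unlabeled
  segs
}
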