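# File-level I/O for sensor streams, annotation events and session manifests.
# Recordings are comma-delimited text with one header row and a time column in
# seconds; acceleration is in units of g so a stationary sensor has norm ~ 1.

ANNOTATION_LABELS <- c("aggressive", "light", "daily_care")

#' Construct an IMU recording
#'
#' One sensor's multichannel time series for one task. Acceleration channels
#' are in g; optional gyroscope channels are in deg/s. Sample times must be
#' uniformly spaced at 1/fs.
#'
#' @param t Sample times in seconds, strictly increasing with step 1/fs.
#' @param ax,ay,az Acceleration channels in g, same length as `t`.
#' @param position Sensor position, one of [sensor_positions()].
#' @param fs Sampling rate in Hz (default 100).
#' @param recording_id,participant_id Identifier strings.
#' @param task_id Task number, integer in 1..18.
#' @param gx,gy,gz Optional angular-velocity channels in deg/s.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(t, ax, ay, az, position, fs = 100,
                          recording_id = "rec", participant_id = "p",
                          task_id = 1L, gx = NULL, gy = NULL, gz = NULL) {
  assert_position(position)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  }
  n <- length(t)
  chans <- list(ax = ax, ay = ay, az = az)
  has_gyro <- !is.null(gx) || !is.null(gy) || !is.null(gz)
  if (has_gyro) {
    if (is.null(gx) || is.null(gy) || is.null(gz)) {
      stop("gyroscope channels must be supplied all together or not at all",
           call. = FALSE)
    }
    chans <- c(chans, list(gx = gx, gy = gy, gz = gz))
  }
  bad <- vapply(chans, function(ch) length(ch) != n, logical(1))
  if (any(bad)) {
    stop("channel length mismatch: ", paste(names(chans)[bad], collapse = ", "),
         " differ from t (n = ", n, ")", call. = FALSE)
  }
  if (n >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-9) {
      stop("timestamps are not uniformly spaced at 1/fs within 1e-9 s",
           call. = FALSE)
    }
  }
  structure(
    c(list(recording_id = recording_id, participant_id = participant_id,
           task_id = as.integer(task_id), position = position, fs = fs,
           t = as.numeric(t)), lapply(chans, as.numeric)),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording %s: %s, participant %s, task %d, %d samples @ %g Hz%s>\n",
              x$recording_id, x$position, x$participant_id, x$task_id,
              length(x$t), x$fs, if (!is.null(x$gx)) ", gyro" else ""))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `imu_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$t)

#' Read a sensor recording from delimited text
#'
#' Expects a CSV with header columns `t,ax,ay,az` and optionally
#' `gx,gy,gz`. Timestamps are validated for uniform 1/fs spacing.
#'
#' @param path Path to the CSV file.
#' @inheritParams imu_recording
#' @return An `imu_recording`.
#' @export
read_recording <- function(path, position, fs = 100,
                           recording_id = basename(path),
                           participant_id = "p", task_id = 1L) {
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "numeric")
  required <- c("t", "ax", "ay", "az")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("recording ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  gyro <- all(c("gx", "gy", "gz") %in% names(df))
  imu_recording(t = df$t, ax = df$ax, ay = df$ay, az = df$az,
                position = position, fs = fs, recording_id = recording_id,
                participant_id = participant_id, task_id = task_id,
                gx = if (gyro) df$gx, gy = if (gyro) df$gy,
                gz = if (gyro) df$gz)
}

#' Write a sensor recording to delimited text
#'
#' Values are written at full double precision so that a read/write
#' round trip agrees channel-wise within 1e-9.
#'
#' @param rec An `imu_recording`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  cols <- c("t", "ax", "ay", "az")
  if (!is.null(rec$gx)) cols <- c(cols, "gx", "gy", "gz")
  df <- as.data.frame(rec[cols])
  data.table::fwrite(df, path)
  invisible(path)
}

#' Construct annotation events
#'
#' Labeled time intervals, relative to the recording's first sample, that
#' provide ground truth for window labeling. Events flagged as operator
#' errors are retained but excluded from labeling.
#'
#' @param label One of `aggressive`, `light`, `daily_care` per event.
#' @param start_s,end_s Interval bounds in seconds, `end_s > start_s >= 0`.
#' @param error_flag Logical; `TRUE` voids the event.
#' @return A data.frame of class `annotation_events`, sorted by `start_s`.
#' @export
annotation_events <- function(label, start_s, end_s,
                              error_flag = rep(FALSE, length(label))) {
  label <- as.character(label)
  bad_label <- !label %in% ANNOTATION_LABELS
  if (any(bad_label)) {
    stop("unknown annotation label(s): ",
         paste(unique(label[bad_label]), collapse = ", "), call. = FALSE)
  }
  if (any(start_s < 0)) stop("event start_s must be >= 0", call. = FALSE)
  if (any(end_s <= start_s)) {
    stop("event end_s must exceed start_s (row ",
         which(end_s <= start_s)[1], ")", call. = FALSE)
  }
  ev <- data.frame(label = label, start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   error_flag = as.logical(error_flag),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$start_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("annotation_events", "data.frame")
  ev
}

#' Read annotation events from CSV
#'
#' Columns: `label,start_s,end_s,error_flag`. Events are returned sorted by
#' start time; malformed intervals or unknown labels are format errors.
#'
#' @param path Path to the annotation CSV.
#' @return An `annotation_events` data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  required <- c("label", "start_s", "end_s", "error_flag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(annotation_events(character(), numeric(), numeric(), logical()))
  }
  annotation_events(df$label, df$start_s, df$end_s, as.logical(df$error_flag))
}

#' Write annotation events to CSV
#' @param events An `annotation_events` data.frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path)
  invisible(path)
}

#' Write a session manifest
#'
#' The manifest is a JSON document with the session id, simulation seed (if
#' any) and one entry per recording: file paths plus the
#' (participant, task, position) triple.
#'
#' @param entries data.frame with columns `recording`, `annotations`,
#'   `participant_id`, `task_id`, `position`.
#' @param path Output path for the manifest JSON.
#' @param session_id Identifier for the session.
#' @param seed Optional simulation seed to record.
#' @return The path, invisibly.
#' @export
write_manifest <- function(entries, path, session_id = "session", seed = NULL) {
  check_manifest_entries(entries)
  doc <- list(session_id = session_id, seed = seed, entries = entries)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

check_manifest_entries <- function(entries) {
  required <- c("recording", "annotations", "participant_id", "task_id",
                "position")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop("manifest entries missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(entries$participant_id, entries$task_id, entries$position)
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, task_id, position) triple in manifest: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  invisible(entries)
}

#' Load a session from a manifest
#'
#' Reads every recording and annotation file referenced by the manifest into
#' memory. Duplicate (participant, task, position) triples and dangling
#' paths are errors.
#'
#' @param manifest_path Path to a manifest JSON written by [write_manifest()].
#' @return A list of class `imu_session` with elements `session_id`, `seed`,
#'   and `entries` (each holding `recording` and `events`).
#' @export
load_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  doc <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  entries <- doc$entries
  if (is.null(entries) || NROW(entries) == 0L) {
    return(structure(list(session_id = doc$session_id %||% "session",
                          seed = doc$seed, entries = list()),
                     class = "imu_session"))
  }
  check_manifest_entries(entries)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  loaded <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    rec_path <- resolve(entries$recording[i])
    ann_path <- resolve(entries$annotations[i])
    for (p in c(rec_path, ann_path)) {
      if (!file.exists(p)) {
        stop("manifest entry ", i, " references missing file: ", p,
             call. = FALSE)
      }
    }
    rec <- read_recording(
      rec_path, position = entries$position[i],
      recording_id = sprintf("%s_t%02d_%s", entries$participant_id[i],
                             entries$task_id[i], entries$position[i]),
      participant_id = entries$participant_id[i],
      task_id = entries$task_id[i]
    )
    loaded[[i]] <- list(recording = rec, events = read_annotations(ann_path))
  }
  structure(list(session_id = doc$session_id %||% "session", seed = doc$seed,
                 entries = loaded),
            class = "imu_session")
}

#' @export
print.imu_session <- function(x, ...) {
  cat(sprintf("<imu_session %s: %d recordings%s>\n", x$session_id,
              length(x$entries),
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  invisible(x)
}
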